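#' Construct a dose-response dataset
#'
#' Observations of a bioactivity readout at a small number of positive
#' concentrations, with the direction of benefit declared per assay (whether
#' a protective drug should increase or decrease the readout) and the control
#' condition the readout was measured against.
#'
#' @param drug drug name.
#' @param assay assay name.
#' @param direction_of_benefit `"increase"` or `"decrease"`.
#' @param concentration_uM positive concentrations in micromolar, one per
#'   observation; at least two distinct values.
#' @param bioactivity bioactivity readouts, same length.
#' @param control_type `"vehicle"` or `"lesion"`.
#' @return an object of class `dose_response_dataset`.
#' @export
dose_response_dataset <- function(drug, assay,
                                  direction_of_benefit = c("increase", "decrease"),
                                  concentration_uM, bioactivity,
                                  control_type = c("vehicle", "lesion")) {
  direction_of_benefit <- match.arg(direction_of_benefit)
  control_type <- match.arg(control_type)
  if (length(concentration_uM) != length(bioactivity)) {
    stop("concentration and bioactivity must have equal length")
  }
  if (any(concentration_uM <= 0)) stop("concentrations must be positive")
  if (length(unique(concentration_uM)) < 2L) {
    stop("need at least two distinct concentrations")
  }
  structure(list(drug = drug, assay = assay,
                 direction_of_benefit = direction_of_benefit,
                 control_type = control_type,
                 concentration_uM = as.numeric(concentration_uM),
                 bioactivity = as.numeric(bioactivity)),
            class = "dose_response_dataset")
}

#' Read dose-response datasets from CSV
#'
#' @param path CSV with columns `drug`, `assay`, `direction_of_benefit`,
#'   `control_type`, `concentration_uM`, `bioactivity`; one dataset per
#'   (drug, assay) pair.
#' @return named list of `dose_response_dataset` objects
#'   (`"drug|assay"` keys).
#' @export
read_dose_response <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  keys <- paste(df$drug, df$assay, sep = "|")
  out <- lapply(split(df, keys), function(s) {
    dose_response_dataset(s$drug[1L], s$assay[1L], s$direction_of_benefit[1L],
                          s$concentration_uM, s$bioactivity, s$control_type[1L])
  })
  out
}

#' Standardize a bioactivity dataset to 10 units per standard deviation
#'
#' Multiplies the bioactivity values by `10 / sd(y)` so that the sample
#' standard deviation of the standardized data is exactly 10 units; the
#' scale factor is stored for back-transformation. Concentrations are
#' unchanged, and the data are not centred.
#'
#' @param dataset a `dose_response_dataset` with at least three observations
#'   and nonzero bioactivity variance.
#' @return the dataset with scaled bioactivity and attributes
#'   `standardized = TRUE`, `scale_factor`.
#' @export
standardize_bioactivity <- function(dataset) {
  y <- dataset$bioactivity
  if (length(y) < 3L) stop("standardization needs at least three observations")
  s <- sd(y)
  if (!is.finite(s) || s == 0) stop("zero bioactivity variance: dataset is unfittable")
  f <- 10 / s
  dataset$bioactivity <- y * f
  attr(dataset, "standardized") <- TRUE
  attr(dataset, "scale_factor") <- f
  dataset
}

#' Undo bioactivity standardization
#' @param dataset a standardized `dose_response_dataset`.
#' @return the dataset on its original bioactivity scale.
#' @export
destandardize_bioactivity <- function(dataset) {
  f <- attr(dataset, "scale_factor")
  if (is.null(f)) stop("dataset is not standardized")
  dataset$bioactivity <- dataset$bioactivity / f
  attr(dataset, "standardized") <- NULL
  attr(dataset, "scale_factor") <- NULL
  dataset
}

#' Sigmoid dose-response mean
#'
#' The four-parameter logistic mean
#' \deqn{\mu(x) = y_1 + \frac{y_0 - y_1}{1 + e^{k (x - EC_{50})}}}
#' with `y0` the bioactivity at the zero-dose asymptote, `y1` at the
#' saturating-dose asymptote (for `k > 0` on a log-concentration axis), `k`
#' the slope and `EC50` the half-effect location. At `x = EC50` the mean is
#' exactly `(y0 + y1) / 2`.
#'
#' @param x concentration axis values (log10 micromolar by default
#'   elsewhere).
#' @param y0,y1,k,ec50 curve parameters.
#' @return mean response at `x`.
#' @export
sigmoid_mean <- function(x, y0, y1, k, ec50) {
  y1 + (y0 - y1) / (1 + exp(k * (x - ec50)))
}

#' Gamma prior on the dose-response fold change
#'
#' The fold change FC = y1 / y0 carries a Gamma(shape 5, rate 5) prior with
#' mean 1, encoding "no effect" as the prior expectation.
#'
#' @param shape,rate gamma parameters (defaults 5 and 5).
#' @return object of class `fc_prior` with fields `shape`, `rate`, `mean`
#'   and functions `density`, `cdf`, `quantile`, `sample`.
#' @export
prior_fold_change <- function(shape = 5, rate = 5) {
  structure(list(
    shape = shape, rate = rate,
    mean = shape / rate,
    density = function(x) dgamma(x, shape = shape, rate = rate),
    cdf = function(q) pgamma(q, shape = shape, rate = rate),
    quantile = function(p) qgamma(p, shape = shape, rate = rate),
    sample = function(n) rgamma(n, shape = shape, rate = rate)
  ), class = "fc_prior")
}

#' Partition fold-change space into protective / neutral / adverse
#'
#' Boundaries are the 0.2 and 0.8 quantiles of the fold-change prior, so the
#' prior probabilities of the three hypotheses are (0.2, 0.6, 0.2) by
#' construction. The neutral interval is the closed central interval; for
#' assays where benefit means a decreased readout, the protective hypothesis
#' is FC below the lower boundary and the adverse hypothesis FC above the
#' upper one; for increase-benefit assays the two are swapped.
#'
#' @param direction_of_benefit `"increase"` or `"decrease"`.
#' @param prior an `fc_prior` (defaults to Gamma(5, 5)).
#' @return object of class `fc_partition`: list of intervals `protective`,
#'   `neutral`, `adverse` (each `c(lower, upper)`), plus `direction` and the
#'   quantile `boundaries`.
#' @export
hypothesis_partition <- function(direction_of_benefit = c("increase", "decrease"),
                                 prior = prior_fold_change()) {
  direction_of_benefit <- match.arg(direction_of_benefit)
  lo <- prior$quantile(0.2)
  hi <- prior$quantile(0.8)
  below <- c(0, lo); above <- c(hi, Inf)
  out <- if (direction_of_benefit == "decrease") {
    list(protective = below, neutral = c(lo, hi), adverse = above)
  } else {
    list(protective = above, neutral = c(lo, hi), adverse = below)
  }
  structure(c(out, list(direction = direction_of_benefit,
                        boundaries = c(lower = lo, upper = hi))),
            class = "fc_partition")
}

#' Classify fold-change values into hypothesis regions
#'
#' The neutral interval is closed, so boundary values count as neutral and
#' the three regions partition the positive axis.
#'
#' @param fc positive fold-change values.
#' @param partition an `fc_partition`.
#' @return factor with levels protective, neutral, adverse.
#' @export
classify_fold_change <- function(fc, partition) {
  lo <- partition$boundaries[["lower"]]
  hi <- partition$boundaries[["upper"]]
  region <- ifelse(fc < lo, "below", ifelse(fc > hi, "above", "neutral"))
  lab <- if (partition$direction == "decrease") {
    c(below = "protective", neutral = "neutral", above = "adverse")
  } else {
    c(below = "adverse", neutral = "neutral", above = "protective")
  }
  factor(unname(lab[region]), levels = c("protective", "neutral", "adverse"))
}
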