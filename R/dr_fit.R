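#' Sampler configuration for the dose-response model
#'
#' @param chains number of MCMC chains.
#' @param draws kept posterior draws per chain.
#' @param warmup adaptation + burn-in iterations per chain.
#' @param thin thinning interval: `draws * thin` iterations are run and
#'   every `thin`-th kept. The conditional one-parameter updates mix slowly
#'   along the correlated (y0, FC, EC50) ridge, so the default keeps 1 in 80.
#' @param seed integer seed; chain RNGs are derived deterministically from
#'   it, so identical data and seed reproduce identical samples.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4L, draws = 1000L, warmup = 1000L,
                           thin = 80L, seed = 1L) {
  stopifnot(chains >= 1L, draws >= 100L, warmup >= 100L, thin >= 1L)
  structure(list(chains = as.integer(chains), draws = as.integer(draws),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Prior configuration for the dose-response model
#'
#' Only the fold-change prior (Gamma shape 5, rate 5) is fixed by the
#' analysis design; the remaining priors are weakly informative defaults.
#' `y0_loc`/`y0_scale` default to the lowest-dose sample mean and 3x the
#' bioactivity standard deviation of the data being fitted ("auto"); supply
#' numbers for a fully pre-specified prior (required for prior-predictive
#' calibration work, where the generating prior must equal the fitted one).
#'
#' @param fc_shape,fc_rate gamma prior on the fold change.
#' @param y0_loc,y0_scale location/scale of the truncated-normal prior on
#'   y0 (`NULL` = data-driven default).
#' @param k_scale half-normal scale of the slope prior.
#' @param sigma_scale half-normal scale of the noise-multiplier prior.
#' @param ec50_pad EC50 is uniform over the observed dose-axis range padded
#'   by this amount on each side.
#' @return list of class `dr_priors`.
#' @export
dr_priors <- function(fc_shape = 5, fc_rate = 5, y0_loc = NULL, y0_scale = NULL,
                      k_scale = 5, sigma_scale = 0.5, ec50_pad = 1) {
  structure(list(fc_shape = fc_shape, fc_rate = fc_rate, y0_loc = y0_loc,
                 y0_scale = y0_scale, k_scale = k_scale,
                 sigma_scale = sigma_scale, ec50_pad = ec50_pad),
            class = "dr_priors")
}

dr_model_string <- "
model {
  for (i in 1:N) {
    mu[i] <- y1 + (y0 - y1) / (1 + exp(k * (x[i] - ec50)))
    tau[i] <- 1 / pow(sigma * mu[i], 2)
    y[i] ~ dnorm(mu[i], tau[i])
  }
  y0 ~ dnorm(y0_loc, y0_prec) T(0,)
  FC ~ dgamma(fc_shape, fc_rate)
  y1 <- FC * y0
  k ~ dnorm(0, k_prec) T(0,)
  ec50 ~ dunif(ec_lo, ec_hi)
  sigma ~ dnorm(0, sigma_prec) T(0,)
}"

#' Fit the Bayesian heteroscedastic sigmoid dose-response model
#'
#' Models standardized bioactivity as
#' \deqn{y \sim N(\mu, \sigma \mu), \quad
#'   \mu = y_1 + \frac{y_0 - y_1}{1 + e^{k (x - EC_{50})}}}
#' with the noise standard deviation proportional to the mean, and the
#' Gamma(5, 5) prior placed directly on the fold change FC = y1 / y0 (y1 is
#' derived as FC * y0, so y0 > 0 keeps mu positive and the noise scale
#' valid). The dose axis is x = log10(concentration in uM) by default, under
#' which y0 is the zero-dose and y1 the saturating-dose asymptote for k > 0.
#' Sampling is delegated to JAGS; the dataset is standardized to 10 units
#' per standard deviation before fitting if it is not already.
#'
#' @param dataset a `dose_response_dataset`.
#' @param priors a [dr_priors()] configuration.
#' @param sampler a [sampler_config()].
#' @param x_mode `"log10"` (default) or `"raw"` concentration axis.
#' @param standardize standardize the dataset before fitting when it is not
#'   already (default `TRUE`). Set to `FALSE` for prior-predictive
#'   calibration work where the generating scale must be preserved.
#' @return object of class `dr_posterior`: list with `samples` (draws x
#'   parameters matrix: FC, y0, y1, k, ec50, sigma), `diagnostics` (per
#'   parameter: rhat, ess, mcse, sd), `dataset`, `x_mode`, `scale_factor`,
#'   `sampler`, `priors`.
#' @export
fit_dose_response <- function(dataset, priors = dr_priors(),
                              sampler = sampler_config(),
                              x_mode = c("log10", "raw"),
                              standardize = TRUE) {
  x_mode <- match.arg(x_mode)
  if (standardize && !isTRUE(attr(dataset, "standardized"))) {
    dataset <- standardize_bioactivity(dataset)
  }
  x <- if (x_mode == "log10") log10(dataset$concentration_uM) else dataset$concentration_uM
  y <- dataset$bioactivity
  y0_loc <- priors$y0_loc
  y0_scale <- priors$y0_scale
  if (is.null(y0_loc)) y0_loc <- mean(y[x == min(x)])
  if (is.null(y0_scale)) y0_scale <- 3 * sd(y)
  data_list <- list(
    N = length(y), x = x, y = y,
    y0_loc = y0_loc, y0_prec = 1 / y0_scale^2,
    fc_shape = priors$fc_shape, fc_rate = priors$fc_rate,
    k_prec = 1 / priors$k_scale^2,
    sigma_prec = 1 / priors$sigma_scale^2,
    ec_lo = min(x) - priors$ec50_pad, ec_hi = max(x) + priors$ec50_pad
  )
  inits <- lapply(seq_len(sampler$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (sampler$seed * 1009L + ch * 31L) %% 2147483647L + 1L)
  })
  jm <- tryCatch(
    rjags::jags.model(textConnection(dr_model_string), data = data_list,
                      inits = inits, n.chains = sampler$chains,
                      n.adapt = sampler$warmup, quiet = TRUE),
    error = function(e) stop("dose-response sampler failed to initialise: ",
                             conditionMessage(e))
  )
  update(jm, n.iter = sampler$warmup)  # burn-in after adaptation
  monitors <- c("FC", "y0", "y1", "k", "ec50", "sigma")
  sl <- rjags::coda.samples(jm, monitors,
                            n.iter = sampler$draws * sampler$thin,
                            thin = sampler$thin, progress.bar = "none")
  combined <- do.call(rbind, lapply(sl, as.matrix))
  combined <- combined[, monitors, drop = FALSE]
  ess <- coda::effectiveSize(sl)[monitors]
  psd <- apply(combined, 2L, sd)
  rhat <- if (sampler$chains >= 2L) {
    coda::gelman.diag(sl, autoburnin = FALSE, multivariate = FALSE)$psrf[monitors, 1L]
  } else {
    setNames(rep(NA_real_, length(monitors)), monitors)
  }
  diagnostics <- data.frame(
    parameter = monitors,
    rhat = as.numeric(rhat),
    ess = as.numeric(ess),
    sd = psd,
    mcse = psd / sqrt(pmax(as.numeric(ess), 1)),
    row.names = NULL
  )
  structure(list(samples = combined, diagnostics = diagnostics,
                 dataset = dataset, x_mode = x_mode,
                 scale_factor = attr(dataset, "scale_factor"),
                 sampler = sampler, priors = priors),
            class = "dr_posterior")
}

#' @export
print.dr_posterior <- function(x, ...) {
  fc <- x$samples[, "FC"]
  cat(sprintf("dr_posterior: %s / %s — %d draws, median FC %.3f (90%% CI %.3f-%.3f)\n",
              x$dataset$drug, x$dataset$assay, nrow(x$samples),
              median(fc), quantile(fc, 0.05), quantile(fc, 0.95)))
  invisible(x)
}

#' Convergence check for a fitted dose-response posterior
#'
#' Fails when any monitored parameter exceeds the Gelman-Rubin rhat
#' threshold, falls below the effective-sample-size threshold, or has a
#' Monte Carlo standard error larger than the given fraction of its
#' posterior standard deviation. Datasets failing the check are excluded
#' from evidence reporting rather than force-interpreted.
#'
#' @param posterior a `dr_posterior`.
#' @param rhat_max maximum acceptable rhat (default 1.01).
#' @param ess_min minimum acceptable effective sample size (default 400).
#' @param mcse_ratio_max maximum mcse / posterior-sd ratio (default 0.1).
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   threshold breaches, empty when passing).
#' @export
check_fit <- function(posterior, rhat_max = 1.01, ess_min = 400,
                      mcse_ratio_max = 0.1) {
  d <- posterior$diagnostics
  reasons <- character()
  bad_rhat <- !is.na(d$rhat) & d$rhat > rhat_max
  if (any(bad_rhat)) {
    reasons <- c(reasons, sprintf("rhat %.3f > %.3f (%s)",
                                  d$rhat[bad_rhat], rhat_max,
                                  d$parameter[bad_rhat]))
  }
  bad_ess <- d$ess < ess_min
  if (any(bad_ess)) {
    reasons <- c(reasons, sprintf("ess %.0f < %d (%s)", d$ess[bad_ess],
                                  ess_min, d$parameter[bad_ess]))
  }
  ratio <- d$mcse / d$sd
  bad_mcse <- is.finite(ratio) & ratio > mcse_ratio_max
  if (any(bad_mcse)) {
    reasons <- c(reasons, sprintf("mcse/sd %.3f > %.3f (%s)", ratio[bad_mcse],
                                  mcse_ratio_max, d$parameter[bad_mcse]))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Posterior hypothesis probabilities, Bayes factor and evidence grade
#'
#' Computes the posterior probabilities of the protective, neutral and
#' adverse hypotheses as the fractions of posterior fold-change samples in
#' the corresponding partition intervals, the posterior-odds Bayes factor
#' BF = P(protective | D) / P(neutral | D), and the evidence statistic
#' 2 ln BF graded on the conventional bands: (2, 6] moderate, (6, 10]
#' strong, above 10 very strong, at or below 2 none. Because the prior odds
#' of protective versus neutral are 1/3 rather than 1, the prior-odds-
#' corrected factor (3 x BF) is reported alongside.
#'
#' @param posterior a `dr_posterior`, or any numeric vector of fold-change
#'   samples.
#' @param partition an `fc_partition`; defaults to the partition for the
#'   dataset's declared direction of benefit when a `dr_posterior` is given.
#' @return object of class `hypothesis_result`: `p_protective`, `p_neutral`,
#'   `p_adverse`, `bf`, `two_log_bf`, `bf_prior_corrected`,
#'   `evidence_grade`, `zero_neutral_caveat`.
#' @export
hypothesis_test <- function(posterior, partition = NULL) {
  if (inherits(posterior, "dr_posterior")) {
    fc <- posterior$samples[, "FC"]
    if (is.null(partition)) {
      partition <- hypothesis_partition(posterior$dataset$direction_of_benefit)
    }
  } else {
    fc <- as.numeric(posterior)
    if (is.null(partition)) stop("partition is required for raw fold-change samples")
  }
  cls <- classify_fold_change(fc, partition)
  p <- as.numeric(table(cls)) / length(fc)
  names(p) <- levels(cls)
  caveat <- p[["neutral"]] == 0
  # 0/0 (no mass in either hypothesis) is NaN, not evidence either way
  bf <- p[["protective"]] / p[["neutral"]]
  structure(list(
    p_protective = p[["protective"]],
    p_neutral = p[["neutral"]],
    p_adverse = p[["adverse"]],
    bf = bf,
    two_log_bf = 2 * log(bf),
    bf_prior_corrected = 3 * bf,  # prior odds protective:neutral are 0.2/0.6
    evidence_grade = evidence_grade(2 * log(bf)),
    zero_neutral_caveat = caveat
  ), class = "hypothesis_result")
}

#' Evidence grade from 2 ln BF
#'
#' @param two_log_bf the evidence statistic, twice the natural-log Bayes
#'   factor.
#' @return one of `"none"`, `"moderate"`, `"strong"`, `"very strong"`.
#' @export
evidence_grade <- function(two_log_bf) {
  vapply(two_log_bf, function(v) {
    if (is.na(v) || is.nan(v)) return(NA_character_)
    if (v <= 2) "none" else if (v <= 6) "moderate"
    else if (v <= 10) "strong" else "very strong"
  }, character(1L))
}

#' @export
print.hypothesis_result <- function(x, ...) {
  cat(sprintf("hypothesis_result: P(protective)=%.3f P(neutral)=%.3f P(adverse)=%.3f | 2lnBF=%.2f (%s)\n",
              x$p_protective, x$p_neutral, x$p_adverse, x$two_log_bf,
              x$evidence_grade))
  invisible(x)
}
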