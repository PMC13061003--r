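test_that("standardization rescales to exactly 10 units per standard deviation", {
  set.seed(1)
  y <- rnorm(12, 100, 5)
  y <- (y - mean(y)) / sd(y) * 5 + 100  # force sd(y) == 5
  ds <- dose_response_dataset("d", "a", "decrease",
                              rep(c(1, 3, 10), each = 4), y, "vehicle")
  std <- standardize_bioactivity(ds)
  expect_equal(attr(std, "scale_factor"), 2)
  expect_equal(sd(std$bioactivity), 10)
  expect_identical(std$concentration_uM, ds$concentration_uM)
  # already at sd 10 -> unchanged values
  ds10 <- ds; ds10$bioactivity <- ds$bioactivity * 2
  expect_equal(standardize_bioactivity(ds10)$bioactivity, ds10$bioactivity)
  # round trip to machine precision
  back <- destandardize_bioactivity(std)
  expect_equal(back$bioactivity, ds$bioactivity, tolerance = 1e-15)
  # degenerate inputs
  dsc <- ds; dsc$bioactivity <- rep(7, 12)
  expect_error(standardize_bioactivity(dsc), "zero bioactivity variance")
  ds2 <- dose_response_dataset("d", "a", "decrease", c(1, 10), c(1, 2), "vehicle")
  expect_error(standardize_bioactivity(ds2), "three observations")
})

test_that("fold-change prior has mean 1 and consistent quantiles", {
  pr <- prior_fold_change()
  expect_equal(pr$mean, 1)
  expect_equal(integrate(function(x) x * pr$density(x), 0, Inf)$value, 1,
               tolerance = 1e-8)
  expect_equal(pr$cdf(Inf), 1)
  # quantiles against numerical inversion of the cdf
  for (p in c(0.2, 0.5, 0.8)) {
    inv <- uniroot(function(q) pr$cdf(q) - p, c(1e-6, 20), tol = 1e-12)$root
    expect_equal(pr$quantile(p), inv, tolerance = 1e-8)
  }
})

test_that("hypothesis partition carries prior mass (0.2, 0.6, 0.2)", {
  pr <- prior_fold_change()
  part <- hypothesis_partition("decrease", pr)
  lo <- part$boundaries[["lower"]]; hi <- part$boundaries[["upper"]]
  expect_equal(pr$cdf(lo), 0.2, tolerance = 1e-12)
  expect_equal(pr$cdf(hi) - pr$cdf(lo), 0.6, tolerance = 1e-12)
  expect_equal(1 - pr$cdf(hi), 0.2, tolerance = 1e-12)
  # the two directions swap protective/adverse, neutral invariant
  inc <- hypothesis_partition("increase", pr)
  expect_equal(inc$neutral, part$neutral)
  expect_equal(inc$protective, part$adverse)
  expect_equal(inc$adverse, part$protective)
})

test_that("Monte-Carlo prior draws land in the partitions at (0.2, 0.6, 0.2)", {
  set.seed(123)
  draws <- prior_fold_change()$sample(1e6)
  part <- hypothesis_partition("decrease")
  freq <- table(classify_fold_change(draws, part)) / 1e6
  expect_equal(as.numeric(freq), c(0.2, 0.6, 0.2), tolerance = 0.01)
})

test_that("sigmoid mean obeys its algebraic identities", {
  set.seed(2)
  for (i in 1:50) {
    y0 <- runif(1, 10, 200); fc <- rgamma(1, 5, 5); k <- abs(rnorm(1, 0, 5))
    ec50 <- runif(1, -1, 2)
    y1 <- fc * y0
    # half-effect at x = EC50
    expect_equal(sigmoid_mean(ec50, y0, y1, k, ec50), (y0 + y1) / 2)
    # asymptotes on the log axis
    expect_equal(sigmoid_mean(-200, y0, y1, k + 1, ec50), y0, tolerance = 1e-8)
    expect_equal(sigmoid_mean(200, y0, y1, k + 1, ec50), y1, tolerance = 1e-8)
  }
  # fold change 1 forces a flat curve regardless of slope
  x <- seq(-2, 2, length.out = 20)
  expect_equal(sigmoid_mean(x, 80, 80, 7, 0.3), rep(80, 20))
})

test_that("the generator's noise scale is proportional to the mean", {
  sc <- synthetic_scenario(
    seed = 11, replicates = 10000L,
    dose_response_truth = data.frame(
      drug = "d", assay = "a", fc_true = 0.4, y0_true = 100, k_true = 3,
      ec50_true = log10(3), sigma_true = 0.08, direction = "decrease"))
  ds <- make_dose_response(sc)$datasets[[1]]
  x <- log10(ds$concentration_uM)
  for (xv in unique(x)) {
    mu <- sigmoid_mean(xv, 100, 40, 3, log10(3))
    v <- var(ds$bioactivity[x == xv])
    expect_equal(sqrt(v), 0.08 * mu, tolerance = 0.05)
    expect_equal(mean(ds$bioactivity[x == xv]), mu, tolerance = 0.01)
  }
  # noiseless limit reproduces the mean exactly
  sc0 <- synthetic_scenario(
    seed = 12, replicates = 2L,
    dose_response_truth = data.frame(
      drug = "d", assay = "a", fc_true = 0.4, y0_true = 100, k_true = 3,
      ec50_true = log10(3), sigma_true = 1e-12, direction = "decrease"))
  ds0 <- make_dose_response(sc0)$datasets[[1]]
  expect_equal(ds0$bioactivity,
               sigmoid_mean(log10(ds0$concentration_uM), 100, 40, 3, log10(3)),
               tolerance = 1e-8)
})

test_that("fits are deterministic under a fixed seed", {
  ds <- simulate_doseresponse(fc = 0.5, seed = 4)
  f1 <- fit_dose_response(ds, sampler = fast_sampler(seed = 7))
  f2 <- fit_dose_response(ds, sampler = fast_sampler(seed = 7))
  expect_identical(f1$samples, f2$samples)
  f3 <- fit_dose_response(ds, sampler = fast_sampler(seed = 8))
  expect_false(identical(f1$samples, f3$samples))
})

test_that("posterior recovers a strong protective fold change", {
  medians <- vapply(1:20, function(s) {
    ds <- simulate_doseresponse(fc = 0.3, sigma = 0.02, k = 6, seed = 300 + s)
    fit <- fit_dose_response(ds, sampler = fast_sampler(seed = s))
    median(fit$samples[, "FC"])
  }, numeric(1))
  expect_gte(median(medians), 0.2)
  expect_lte(median(medians), 0.45)
})

test_that("flat-truth data keep 1 inside the central posterior interval", {
  covered <- vapply(1:10, function(s) {
    ds <- simulate_doseresponse(fc = 1, sigma = 0.05, seed = 500 + s)
    fit <- fit_dose_response(ds, sampler = fast_sampler(seed = s))
    ci <- quantile(fit$samples[, "FC"], c(0.05, 0.95))
    ci[1] <= 1 && 1 <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 8)
})

test_that("check_fit enumerates threshold breaches", {
  ideal <- list(diagnostics = data.frame(
    parameter = c("FC", "y0"), rhat = c(1.000, 1.001), ess = c(4000, 3500),
    sd = c(0.1, 5), mcse = c(0.001, 0.05)))
  expect_true(check_fit(ideal)$pass)
  bad <- ideal
  bad$diagnostics$rhat[1] <- 2.0
  res <- check_fit(bad)
  expect_false(res$pass)
  expect_match(res$reasons, "rhat", all = FALSE)
  low <- ideal
  low$diagnostics$ess[2] <- 50
  low$diagnostics$mcse[2] <- 5 / sqrt(50)
  res2 <- check_fit(low)
  expect_false(res2$pass)
  expect_match(res2$reasons, "ess", all = FALSE)
  expect_match(res2$reasons, "mcse", all = FALSE)
})

test_that("a well-specified strong-signal fit passes diagnostics given a long chain", {
  ds <- simulate_doseresponse(fc = 0.3, sigma = 0.02, k = 6, seed = 21)
  fit <- fit_dose_response(ds, sampler = sampler_config(thin = 300L, seed = 21))
  chk <- check_fit(fit)
  expect_true(chk$pass)
  ht <- hypothesis_test(fit)
  expect_gt(ht$two_log_bf, 2)
  expect_true(ht$evidence_grade %in% c("moderate", "strong", "very strong"))
})

test_that("hypothesis_test computes probabilities, Bayes factor and grade", {
  part <- hypothesis_partition("decrease")
  lo <- part$boundaries[["lower"]]; hi <- part$boundaries[["upper"]]
  # all samples neutral
  ht <- hypothesis_test(rep((lo + hi) / 2, 1000), part)
  expect_equal(ht$p_neutral, 1)
  expect_equal(ht$bf, 0)
  expect_identical(ht$evidence_grade, "none")
  expect_equal(ht$p_protective + ht$p_neutral + ht$p_adverse, 1, tolerance = 1e-9)
  # equal protective and neutral mass -> BF 1, 2lnBF 0
  ht2 <- hypothesis_test(c(rep(lo / 2, 500), rep(1, 500)), part)
  expect_equal(ht2$bf, 1)
  expect_equal(ht2$two_log_bf, 0)
  expect_equal(ht2$bf_prior_corrected, 3)
  # no neutral mass -> infinite posterior odds with caveat
  ht3 <- hypothesis_test(rep(lo / 2, 100), part)
  expect_true(is.infinite(ht3$bf))
  expect_true(ht3$zero_neutral_caveat)
  # grade bands
  expect_identical(evidence_grade(c(1, 3, 7, 11)),
                   c("none", "moderate", "strong", "very strong"))
})
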