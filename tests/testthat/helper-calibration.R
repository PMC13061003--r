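# Helpers for Bayesian calibration runs: prior draws that exactly match the
# model's fully specified priors, and the rank statistic used for
# simulation-based calibration.

# fixed, data-independent priors used for calibration (the fitting default
# centres y0 on the data; calibration requires the generating prior and the
# fitted prior to coincide)
calib_priors <- function() {
  dr_priors(y0_loc = 100, y0_scale = 30)
}

rtrunc_norm_pos <- function(mean, sd) {
  repeat {
    v <- rnorm(1, mean, sd)
    if (v > 0) return(v)
  }
}

# one joint draw from the model's prior at the calibration settings
draw_prior_params <- function() {
  list(y0 = rtrunc_norm_pos(100, 30),
       fc = rgamma(1, 5, 5),
       k = abs(rnorm(1, 0, 5)),
       ec50 = runif(1, log10(1) - 1, log10(10) + 1),
       sigma = abs(rnorm(1, 0, 0.5)))
}

# simulate a dataset from given parameters at the standard 3-dose design
simulate_from_params <- function(pars, doses = c(1, 3, 10), replicates = 3,
                                 direction = "decrease") {
  x <- rep(log10(doses), each = replicates)
  mu <- sigmoid_mean(x, pars$y0, pars$fc * pars$y0, pars$k, pars$ec50)
  y <- rnorm(length(x), mu, pars$sigma * mu)
  dose_response_dataset("calib", "calib", direction,
                        rep(doses, each = replicates), y, "vehicle")
}

# SBC rank of the true fold change among L approximately independent
# posterior draws (evenly spaced through the pooled chains)
sbc_rank <- function(fc_samples, fc_true, L = 19) {
  idx <- round(seq(1, length(fc_samples), length.out = L))
  sum(fc_samples[idx] < fc_true)
}
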