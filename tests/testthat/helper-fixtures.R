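# Shared small fixtures, built in code at load time.

# path graph A - B - C - D
path4 <- function() {
  load_interactome(cbind(c("A", "B", "C"), c("B", "C", "D")))
}

# a small cached synthetic scenario shared by several test files
shared_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- synthetic_scenario(seed = 42, n_genes = 300, n_drugs = 40,
                               n_disease_genes = 15,
                               proximity_signal = 0.5, phase_signal = 0.8)
      cache <<- suppressMessages(generate_scenario(sc))
    }
    cache
  }
})

# quick sampler settings for tests that only need a valid posterior
fast_sampler <- function(seed = 1L, chains = 2L) {
  sampler_config(chains = chains, draws = 500L, warmup = 500L,
                 thin = 4L, seed = seed)
}

# simulate one dataset from given curve parameters on the log10-uM axis
simulate_doseresponse <- function(fc, y0 = 100, k = 3, ec50 = log10(3),
                                  sigma = 0.05, doses = c(1, 3, 10),
                                  replicates = 5,
                                  direction = "decrease", seed = 1) {
  set.seed(seed)
  x <- rep(log10(doses), each = replicates)
  mu <- sigmoid_mean(x, y0, fc * y0, k, ec50)
  y <- rnorm(length(x), mu, sigma * mu)
  dose_response_dataset("drug", "assay", direction,
                        rep(doses, each = replicates), y, "vehicle")
}
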