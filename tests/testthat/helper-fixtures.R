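# shared fixtures for the test suite

fix_m1 <- model_config("M1")
fix_m2 <- model_config("M2")
fix_median <- sflt_median_params()
fix_units <- unit_map("synthetic-hornig" = 1e-5)

# draw random parameter sets in the dynamically stable regime of the delay
# model ((beta+gamma)*tau below the delayed-feedback oscillation threshold),
# where the experimentally relevant dynamics live
draw_stable_params <- function(n, seed, tau_range = c(0.25, 4)) {
  withr::with_seed(seed, {
    out <- list()
    while (length(out) < n) {
      p <- list(alpha = 10 ^ runif(1, 3, 6), beta = 10 ^ runif(1, -2, 0),
                gamma = 10 ^ runif(1, -2, 0), delta = 10 ^ runif(1, -1.7, 0),
                tau = runif(1, tau_range[1], tau_range[2]))
      if ((p$beta + p$gamma) * p$tau < 1.2) {
        out[[length(out) + 1]] <- do.call(sflt_params, p)
      }
    }
    out
  })
}
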