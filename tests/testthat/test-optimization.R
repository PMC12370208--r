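test_that("cost is the unweighted sum of squared residuals over retained points", {
  data <- generate_study(synthetic_study_spec(sigma = 0.1, seed = 9))
  # recompute independently from per-dataset predictions
  sims <- list(
    constitutive = simulate_constitutive(fix_m2, fix_median, duration = 72),
    pulse_chase = simulate_pulse_chase(fix_m2, fix_median))
  kept <- data[!data$omit_flag, ]
  expected <- 0
  for (key in unique(paste(kept$study_id, kept$species))) {
    ds <- kept[paste(kept$study_id, kept$species) == key, ]
    pred <- predict_on_dataset(sims[[ds$scenario[1]]], ds, fix_units)
    expected <- expected + sum((pred$predicted - ds$value) ^ 2)
  }
  expect_equal(sflt_cost(fix_m2, fix_median, data, fix_units), expected,
               tolerance = 1e-10)
  # exact predictions give zero cost: noise-free data from the same truth
  d0 <- generate_study(synthetic_study_spec(sigma = 0, seed = 9))
  expect_lt(sflt_cost(fix_m2, fix_median, d0, fix_units), 1e-4)
  # relative-residual variant divides by the observation
  c_rel <- sflt_cost(fix_m2, fix_median, data, fix_units,
                     relative_residuals = TRUE)
  expect_gt(c_rel, 0)
  expect_false(isTRUE(all.equal(c_rel,
                                sflt_cost(fix_m2, fix_median, data,
                                          fix_units))))
})

test_that("initial guesses are log-uniform, in-bounds and seed-reproducible", {
  rg <- sampling_ranges()
  g1 <- sample_initial_guesses(fix_m2, rg, n = 500, seed = 42)
  g2 <- sample_initial_guesses(fix_m2, rg, n = 500, seed = 42)
  expect_identical(g1, g2)
  expect_named(g1, c("alpha", "beta", "gamma", "delta", "tau"))
  for (par in names(g1)) {
    lo <- rg$low[rg$parameter == par]
    hi <- rg$high[rg$parameter == par]
    expect_true(all(g1[[par]] >= lo & g1[[par]] <= hi))
  }
  # log-uniform centering: median of a (1e-3, 10) range is near 0.1
  expect_lt(abs(log10(median(g1$beta)) - log10(0.1)), log10(3))
  expect_error(sampling_ranges(beta = c(1, 0.5)), "low < high")
  expect_error(sample_initial_guesses(fix_m2, rg, n = 0), "n must be")
})

test_that("fitting noise-free data recovers the identifiable quantities", {
  d0 <- generate_study(synthetic_study_spec(sigma = 0, seed = 13))
  start <- fix_median
  start$alpha <- start$alpha * 3   # perturbed start, same structure
  start$delta <- start$delta * 2
  f <- sflt_fit(fix_m2, d0, fix_units, guess = start, max_iter = 200)
  expect_true(f$converged)
  expect_lt(f$cost, 1e-6)
  cc <- compound_constants(f$params)
  truth_cc <- compound_constants(fix_median)
  expect_equal(f$params$delta, fix_median$delta, tolerance = 0.02)
  expect_equal(f$params$tau, fix_median$tau, tolerance = 0.02)
  expect_equal(cc$c1, truth_cc$c1, tolerance = 0.02)
  expect_equal(cc$c2, truth_cc$c2, tolerance = 0.02)
  # descent contract: starting at the optimum cannot increase the cost
  f2 <- sflt_fit(fix_m2, d0, fix_units, guess = f$params)
  expect_lte(f2$cost, f$cost + 1e-8)
  expect_error(sflt_fit(fix_m2, d0, fix_units,
                        guess = c(alpha = 1, beta = 0.1, gamma = 0.1,
                                  delta = 0.1, tau = 1)),
               "outside the sampling ranges")
})

test_that("cost filtering retains runs within the tolerance of the minimum", {
  fits <- tibble::tibble(model = "M2", run = 1:3,
                         alpha = 1, beta = 1, gamma = 1, delta = 1, tau = 1,
                         epsilon = 0, kappa = 0,
                         cost = c(1.0, 1.05, 1.2), converged = TRUE)
  class(fits) <- c("sflt_fits", class(fits))
  kept <- filter_fits(fits, tolerance = 0.10)
  expect_equal(kept$run, 1:2)
  all_equal <- dplyr::mutate(fits, cost = 2)
  expect_equal(nrow(filter_fits(all_equal)), 3)
  none <- dplyr::mutate(fits, converged = FALSE)
  expect_error(filter_fits(none), "empty ensemble")
})

test_that("AICc matches hand evaluation and penalizes added parameters", {
  expect_equal(aicc(26, 26, 6), 12 + 84 / 19, tolerance = 1e-12)
  expect_equal(aicc(26, 26, 5), 13, tolerance = 1e-12)
  # independent spreadsheet-style evaluation on random triples
  withr::with_seed(31, {
    for (i in 1:10) {
      C <- runif(1, 0.1, 100); n <- sample(15:60, 1); k <- sample(3:8, 1)
      independent <- n * (log(C) - log(n)) + 2 * k +
        (2 * k ^ 2 + 2 * k) / (n - k - 1)
      expect_equal(aicc(C, n, k), independent, tolerance = 1e-9)
    }
  })
  # equal costs: larger k scores strictly worse
  expect_gt(aicc(5, 26, 7), aicc(5, 26, 6))
  expect_error(aicc(0, 26, 6), "cost")
  expect_error(aicc(1, 7, 6), "correction")
})

test_that("multistart is deterministic under a fixed seed and serializes", {
  d <- generate_study(synthetic_study_spec(sigma = 0.1, seed = 17))
  f1 <- multistart_fit(fix_m2, d, fix_units, n_starts = 2, seed = 5,
                       max_iter = 30)
  f2 <- multistart_fit(fix_m2, d, fix_units, n_starts = 2, seed = 5,
                       max_iter = 30)
  expect_equal(as.data.frame(f1), as.data.frame(f2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fits(f1, path)
  back <- read_fits(path)
  expect_equal(back$cost, f1$cost)
  expect_equal(back$alpha, f1$alpha)
})
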