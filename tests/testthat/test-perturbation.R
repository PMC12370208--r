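test_that("null perturbation and closed-form genetic production inhibition", {
  inh0 <- simulate_inhibition(fix_m2, fix_median, "beta", 0, "chemical")
  expect_equal(inh0$fold_changes$fold_change, rep(1, 4))
  # genetic inhibition of alpha: both pools scale exactly by 1 - f
  for (f in c(0.25, 0.9)) {
    inh <- simulate_inhibition(fix_m2, fix_median, "alpha", f, "genetic")
    expect_equal(inh$fold_changes$fold_change, rep(1 - f, 4),
                 tolerance = 1e-6)
  }
  expect_error(simulate_inhibition(fix_m2, fix_median, "alpha", 1.2,
                                   "genetic"), "fraction")
  expect_error(simulate_inhibition(fix_m2, fix_median, "rho", 0.5,
                                   "genetic"), "target")
})

test_that("chemical inhibition of delta and tau leave the intracellular pool alone", {
  inh_d <- simulate_inhibition(fix_m2, fix_median, "delta", 0.9, "chemical")
  fc <- inh_d$fold_changes
  expect_equal(fc$fold_change[fc$species == "I"], c(1, 1))
  expect_true(all(fc$fold_change[fc$species == "X"] > 1))
  # the maturation delay is invisible during constitutive secretion
  inh_t <- simulate_inhibition(fix_m2, fix_median, "tau", 0.9, "chemical")
  expect_equal(inh_t$fold_changes$fold_change, rep(1, 4), tolerance = 1e-3)
})

test_that("chemical production inhibition overshoots before the new steady state", {
  inh <- simulate_inhibition(fix_m2, fix_median, "alpha", 0.9, "chemical")
  tc <- inh$timecourse
  # X rises above its final value early, then declines toward it
  final <- tc$X[nrow(tc)]
  expect_gt(max(tc$X), final * 1.1)
  expect_lt(which.max(tc$X), nrow(tc) / 2)
  # genetic inhibition instead approaches the lowered steady state from below
  inh_g <- simulate_inhibition(fix_m2, fix_median, "alpha", 0.9, "genetic")
  expect_true(all(diff(inh_g$timecourse$X) > -1e-9))
})

test_that("chemical and genetic modes converge at late readouts for beta, gamma, delta", {
  for (target in c("beta", "gamma", "delta")) {
    chem <- simulate_inhibition(fix_m2, fix_median, target, 0.6, "chemical",
                                readout_times = 72)
    gen <- simulate_inhibition(fix_m2, fix_median, target, 0.6, "genetic",
                               readout_times = 72)
    fc_c <- chem$fold_changes$fold_change[chem$fold_changes$species == "X"]
    fc_g <- gen$fold_changes$fold_change[gen$fold_changes$species == "X"]
    expect_equal(fc_c, fc_g, tolerance = 0.02)
  }
})

test_that("inhibition inversion round-trips and flags infeasible ratios", {
  expect_equal(estimate_inhibition(fix_m2, fix_median, "beta", "chemical",
                                   "X", 18, observed_ratio = 1)$fraction, 0)
  # closed-form case: genetic alpha with I readout, ratio 0.25 -> f = 0.75
  est <- estimate_inhibition(fix_m2, fix_median, "alpha", "genetic", "I",
                             18, observed_ratio = 0.25)
  expect_equal(est$fraction, 0.75, tolerance = 1e-3)
  expect_equal(est$feasibility, "feasible")
  # round trip through the simulator
  for (target in c("beta", "gamma")) {
    sim <- simulate_inhibition(fix_m2, fix_median, target, 0.6, "chemical",
                               readout_times = 18)
    r <- sim$fold_changes$fold_change[sim$fold_changes$species == "X" &
                                        sim$fold_changes$time_h == 18]
    est <- estimate_inhibition(fix_m2, fix_median, target, "chemical", "X",
                               18, observed_ratio = r)
    expect_equal(est$fraction, 0.6, tolerance = 1e-3)
  }
  # full secretion block drives X18h to zero, so even a tiny positive ratio
  # is attainable (near-complete inhibition)
  deep <- estimate_inhibition(fix_m2, fix_median, "beta", "chemical", "X",
                              18, observed_ratio = 1e-4)
  expect_equal(deep$feasibility, "feasible")
  expect_gt(deep$fraction, 0.95)
  # the intracellular rise under beta inhibition is bounded (at most about
  # c2/gamma-fold), so a large observed I increase exceeds full inhibition
  full <- estimate_inhibition(fix_m2, fix_median, "beta", "chemical", "I",
                              18, observed_ratio = 10)
  expect_equal(full$feasibility, "exceeds_full_inhibition")
  # wrong side of 1: inhibiting beta cannot increase extracellular sFLT1
  wrong <- estimate_inhibition(fix_m2, fix_median, "beta", "chemical", "X",
                               18, observed_ratio = 1.5)
  expect_equal(wrong$feasibility, "wrong_direction")
  expect_error(estimate_inhibition(fix_m2, fix_median, "beta", "chemical",
                                   "X", 18, observed_ratio = -1),
               "observed_ratio")
})

test_that("inhibition responses are monotone in f over the grid", {
  f_grid <- seq(0, 1, by = 0.1)
  for (target in c("alpha", "beta", "gamma", "delta")) {
    curves <- inhibition_response_curves(
      fix_m2, beta_grid(7269, 0.1727, delta = fix_median$delta,
                        tau = fix_median$tau, fractions = c(0.2, 1)),
      target = target, mode = "chemical",
      readouts = tibble::tibble(species = "X", time_h = 18),
      f_grid = f_grid)
    for (set in unique(curves$base_set)) {
      y <- curves$fold_change[curves$base_set == set]
      d <- diff(y)
      expect_true(all(d >= -1e-9) || all(d <= 1e-9))
    }
  }
})

test_that("the beta grid spans the manifold with shared X and scaled I", {
  cc <- compound_constants(fix_median)
  grid <- beta_grid(cc$c1, cc$c2, delta = fix_median$delta,
                    tau = fix_median$tau)
  expect_equal(grid$beta_frac, c(0.2, 0.4, 0.6, 0.8, 1.0))
  expect_equal(grid$gamma[5], 0)
  expect_equal(grid$alpha * grid$beta, rep(cc$c1, 5), tolerance = 1e-12)
  expect_equal(grid$beta + grid$gamma, rep(cc$c2, 5), tolerance = 1e-12)
})

test_that("response curves for alpha coincide across base sets; beta responses diverge in I", {
  cc <- compound_constants(fix_median)
  grid <- beta_grid(cc$c1, cc$c2, delta = fix_median$delta,
                    tau = fix_median$tau, fractions = c(0.2, 0.6, 1))
  curves_a <- inhibition_response_curves(
    fix_m2, grid, target = "alpha", mode = "chemical",
    readouts = tibble::tibble(species = "X", time_h = 18),
    f_grid = c(0, 0.5, 0.9))
  spread <- curves_a |>
    dplyr::group_by(f) |>
    dplyr::summarise(s = diff(range(fold_change)))
  expect_lt(max(spread$s), 1e-6)
  expect_equal(curves_a$fold_change[curves_a$f == 0], rep(1, 3))
  # higher-beta base sets respond more strongly to beta inhibition in I
  curves_b <- inhibition_response_curves(
    fix_m2, grid, target = "beta", mode = "genetic",
    readouts = tibble::tibble(species = "I", time_h = 18),
    f_grid = c(0.8))
  y <- curves_b$fold_change[order(curves_b$base_set)]
  expect_true(all(diff(y) > 0))
})
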