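test_that("parameter sets validate their domain and serialize round-trip", {
  expect_error(sflt_params(-1, 0.1, 0.1, 0.1), "non-negative")
  expect_error(sflt_params(NA, 0.1, 0.1, 0.1), "finite")
  p <- sflt_params(1e4, 0.12, 0.05, 0.08, tau = 1.5)
  expect_s3_class(p, "sflt_params")
  path <- withr::local_tempfile(fileext = ".cfg")
  write_params(p, path, config = model_config("M2"))
  back <- read_params(path)
  expect_equal(unlist(back$params), unlist(p))
  expect_equal(back$config$label, "M2")
})

test_that("the model family enumerates the eight flag combinations once", {
  fam <- model_family()
  expect_equal(nrow(fam), 8)
  combos <- paste(fam$include_delay, fam$include_internalization,
                  fam$include_production_decay)
  expect_equal(length(unique(combos)), 8)
  expect_equal(fam$k_params, 4L + fam$include_delay +
                 fam$include_internalization + fam$include_production_decay)
  m1 <- model_config("M1")
  expect_false(any(c(m1$include_delay, m1$include_internalization,
                     m1$include_production_decay)))
  m2 <- model_config("M2")
  expect_true(m2$include_delay)
  expect_false(m2$include_internalization || m2$include_production_decay)
  expect_equal(model_config(include_delay = TRUE)$label, "M2")
})

test_that("the right-hand side matches hand evaluation of the rate terms", {
  # null dynamics
  p0 <- sflt_params(0, 0, 0, 0)
  r <- secretion_rhs(fix_m1, p0, I = 123, X = 456)
  expect_equal(c(r$dI_dt, r$dX_dt), c(0, 0))
  # plain ODE model, production on
  p <- sflt_params(100, 0.1, 0.1, 0.05)
  r <- secretion_rhs(fix_m1, p, I = 1000, X = 0)
  expect_equal(r$dI_dt, -100)
  expect_equal(r$dX_dt, 100)
  # delay model: rates read the delayed intracellular amount
  pd <- sflt_params(100, 0.1, 0.1, 0.05, tau = 2)
  r <- secretion_rhs(fix_m2, pd, I = 500, X = 40, delayed_I = 1000)
  expect_equal(r$dI_dt, 100 - 0.2 * 1000)
  expect_equal(r$dX_dt, 0.1 * 1000 - 0.05 * 40)
  # chase with no production-decay process: production is 0, not alpha
  r <- secretion_rhs(fix_m2, pd, I = 500, X = 0, delayed_I = 500,
                     phase = "chase", t_since_chase = 1)
  expect_equal(r$dI_dt, -0.2 * 500)
  # chase with production decay: alpha * exp(-kappa t)
  m3 <- model_config(include_production_decay = TRUE)
  pk <- sflt_params(100, 0.1, 0.1, 0.05, kappa = 0.5)
  r <- secretion_rhs(m3, pk, I = 0, X = 0, phase = "chase",
                     t_since_chase = 2)
  expect_equal(r$dI_dt, 100 * exp(-1))
  # contract errors
  expect_error(secretion_rhs(fix_m1, p, I = -1, X = 0), "non-negative")
  expect_error(secretion_rhs(fix_m1, p, I = 1, X = 0, delayed_I = 2),
               "delayed_I")
  expect_error(secretion_rhs(fix_m1, pd, I = 1, X = 0), "excludes")
})

test_that("closed-form steady states and characteristic times are exact", {
  p <- sflt_params(1e4, 0.1, 0.1, 0.1)
  ss <- steady_state(p)
  expect_equal(ss$I_ss, 5e4)
  expect_equal(ss$X_ss, 5e4)
  expect_equal(steady_state(sflt_params(0, 0.1, 0.2, 0.3))$I_ss, 0)
  ct <- characteristic_times(p)
  expect_equal(ct$T50_I, log(2) / 0.2)
  expect_equal(ct$T50_X, log(2) / 0.1)
  # doubling delta halves T50_X
  ct2 <- characteristic_times(sflt_params(1e4, 0.1, 0.1, 0.2))
  expect_equal(ct2$T50_X, ct$T50_X / 2)
  expect_error(steady_state(sflt_params(1, 0, 0, 1)), "steady state")
  expect_error(characteristic_times(sflt_params(1, 0.1, 0.1, 0)),
               "steady state")
  # median calibrated set: I_ss about 8.2e5 #/cell, T50_X about 12.07 h
  expect_equal(steady_state(fix_median)$I_ss, 8.2e5, tolerance = 0.005)
  expect_equal(characteristic_times(fix_median)$T50_X, 12.07,
               tolerance = 1e-3)
})

test_that("compound constants and their inversion round-trip", {
  cc <- compound_constants(fix_median)
  expect_equal(cc$c1, 7.269e3, tolerance = 1e-3)
  expect_equal(cc$c2, 1.727e-1, tolerance = 1e-3)
  expect_equal(compound_constants(sflt_params(5, 0, 0.3, 1)),
               tibble::tibble(c1 = 0, c2 = 0.3))
  # inversion: alpha = c1/beta, gamma = c2 - beta
  p <- parameters_from_beta(7269, 0.1727, beta = 0.2 * 0.1727,
                            delta = 0.057, tau = 1.96)
  expect_equal(p$alpha, 7269 / 0.03454, tolerance = 1e-10)
  expect_equal(p$gamma, 0.1727 - 0.03454)
  # recovering the median alpha and gamma from the compound medians
  p2 <- parameters_from_beta(7.269e3, 1.727e-1, beta = fix_median$beta,
                             delta = fix_median$delta, tau = fix_median$tau)
  expect_equal(p2$alpha, fix_median$alpha, tolerance = 1e-3)
  expect_equal(p2$gamma, fix_median$gamma, tolerance = 1e-3)
  # boundary and infeasible cases
  expect_equal(parameters_from_beta(10, 0.2, 0.2, delta = 0.1)$gamma, 0)
  expect_error(parameters_from_beta(10, 0.2, 0.3, delta = 0.1), "infeasible")
  expect_error(parameters_from_beta(10, 0.2, 0, delta = 0.1), "infeasible")
  # round trip through compound_constants for random sets
  for (p in draw_stable_params(5, seed = 11)) {
    cc <- compound_constants(p)
    back <- parameters_from_beta(cc$c1, cc$c2, p$beta, delta = p$delta,
                                 tau = p$tau)
    expect_equal(back$alpha, p$alpha, tolerance = 1e-12)
    expect_equal(back$gamma, p$gamma, tolerance = 1e-12)
  }
})

test_that("steady-state identity I_ss = alpha/c2 holds on the beta grid", {
  cc <- compound_constants(fix_median)
  grid <- beta_grid(cc$c1, cc$c2, delta = fix_median$delta,
                    tau = fix_median$tau)
  for (i in seq_len(nrow(grid))) {
    p <- sflt_params(grid$alpha[i], grid$beta[i], grid$gamma[i],
                     grid$delta[i], grid$tau[i])
    expect_equal(steady_state(p)$I_ss, grid$alpha[i] / cc$c2,
                 tolerance = 1e-12)
    expect_equal(steady_state(p)$I_ss, cc$c1 / (grid$beta[i] * cc$c2),
                 tolerance = 1e-12)
  }
})
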