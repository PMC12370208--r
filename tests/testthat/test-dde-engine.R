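test_that("method-of-steps solution matches the brute-force delayed RK4 oracle", {
  sets <- draw_stable_params(5, seed = 21)
  for (p in sets) {
    sol <- integrate_model(fix_m2, p, y0 = c(0, 0), t_span = c(0, 24))
    orc <- oracle_at_minutes(oracle_rk4(p, 0, 0, 24), 24)
    expect_lt(rel_dev(sol$timecourse$I, orc$I), 0.005)
    expect_lt(rel_dev(sol$timecourse$X, orc$X), 0.005)
  }
})

test_that("vanishing delay reproduces the ODE limit", {
  p0 <- fix_median
  p0$tau <- 0
  base <- integrate_model(fix_m1, p0, c(0, 0), c(0, 24))
  # below the solver's delay threshold: identical ODE path
  p_tiny <- fix_median
  p_tiny$tau <- 1e-9
  tiny <- integrate_model(fix_m2, p_tiny, c(0, 0), c(0, 24))
  expect_lt(rel_dev(tiny$timecourse$X, base$timecourse$X), 1e-3)
  # a small but genuinely integrated delay stays within 0.1%; shared
  # tolerances so the comparison sees the delay, not tolerance defaults.
  # (a delay tau shifts the early quadratic X ramp by a relative 2*tau/t,
  # so tau must sit well below the comparison horizon)
  tight <- solver_settings(abs_tol = 1e-8, rel_tol = 1e-6)
  base_t <- integrate_model(fix_m1, p0, c(0, 0), c(0, 24), settings = tight)
  p_small <- fix_median
  p_small$tau <- 1e-4
  small <- integrate_model(fix_m2, p_small, c(0, 0), c(0, 24),
                           settings = tight)
  expect_lt(rel_dev(small$timecourse$I, base_t$timecourse$I), 1e-3)
  expect_lt(rel_dev(small$timecourse$X, base_t$timecourse$X), 1e-3)
})

test_that("pure accumulation has the linear closed form", {
  p <- sflt_params(250, 0, 0, 0)
  sol <- integrate_model(fix_m1, p, c(10, 0), c(0, 4))
  expect_equal(sol$timecourse$I, 10 + 250 * sol$timecourse$time_h,
               tolerance = 1e-9)
  expect_equal(sol$timecourse$X, rep(0, nrow(sol$timecourse)))
})

test_that("a constant steady-state history is a fixed point of the dynamics", {
  I_ss <- steady_state(fix_median)$I_ss
  sol <- integrate_model(fix_m2, fix_median, c(I_ss, 0), c(0, 72),
                         pre_history_I = I_ss)
  expect_lt(max(abs(sol$timecourse$I / I_ss - 1)), 0.005)
})

test_that("independent packaged DDE solver agrees on the constitutive phase", {
  skip_if_not_installed("deSolve")
  p <- fix_median
  I_ss <- steady_state(p)$I_ss
  mine <- integrate_model(fix_m2, p, c(I_ss, 0), c(0, 48),
                          pre_history_I = I_ss)
  rhs <- function(t, y, parms) {
    Id <- if (t < parms$tau) I_ss else deSolve::lagvalue(t - parms$tau, 1)
    list(c(parms$alpha - (parms$beta + parms$gamma) * Id,
           parms$beta * Id - parms$delta * y[2]))
  }
  ref <- deSolve::dede(y = c(I_ss, 0), times = mine$timecourse$time_h,
                       func = rhs, parms = unclass(p),
                       atol = 1e-8, rtol = 1e-8)
  expect_lt(rel_dev(mine$timecourse$I, ref[, 2]), 0.005)
  expect_lt(rel_dev(mine$timecourse$X, ref[, 3]), 0.005)
})

test_that("steady-state pre-simulation converges to the closed form", {
  # worked example: alpha = 10,000, beta = gamma = delta = 0.1
  ss <- run_to_steady_state(fix_m1, sflt_params(1e4, 0.1, 0.1, 0.1))
  expect_equal(ss$I, 5e4, tolerance = 0.01)
  # production-free system converges in the first chunk
  ss0 <- run_to_steady_state(fix_m1, sflt_params(0, 0.1, 0.1, 0.1))
  expect_equal(ss0$I, 0)
  expect_equal(ss0$chunks, 1L)
  # median calibrated set reaches I_ss about 8.2e5
  ss2 <- run_to_steady_state(fix_m2, fix_median)
  expect_equal(ss2$I, 8.2e5, tolerance = 0.01)
  expect_error(run_to_steady_state(fix_m1, sflt_params(1, 0, 0, 1)),
               "beta \\+ gamma")
})

test_that("the constitutive protocol applies the media change correctly", {
  tc <- simulate_constitutive(fix_m2, fix_median, duration = 24)
  expect_equal(tc$X[1], 0)                      # media change zeroes X
  expect_equal(nrow(tc), 24 * 60 + 1)           # 1-minute reporting grid
  expect_true(all(diff(tc$X) > -1e-9))          # X non-decreasing
  expect_lt(max(tc$X), steady_state(fix_median)$X_ss)  # approach from below
  I_ss <- run_to_steady_state(fix_m2, fix_median)$I
  expect_lt(max(abs(tc$I / I_ss - 1)), 0.005)   # I stays at steady state
  expect_true(all(tc$I >= 0 & tc$X >= 0))
})

test_that("the pulse-chase protocol tracks only the labeled cohort", {
  tc <- simulate_pulse_chase(fix_m2, fix_median)
  chase <- tc[tc$phase == "chase", ]
  expect_equal(chase$X[1], 0)
  expect_equal(min(tc$time_h), -1 / 3, tolerance = 1e-9)
  # no labeled protein can exit before maturing: X = 0 until tau - 20 min
  early <- chase[chase$time_h < fix_median$tau - 1 / 3 - 1e-9, ]
  expect_true(all(early$X == 0))
  # without the delay, X rises immediately after the media change
  p0 <- fix_median
  p0$tau <- 0
  tc0 <- simulate_pulse_chase(fix_m1, p0)
  expect_gt(tc0$X[tc0$phase == "chase"][5], 0)
  # total labeled protein is non-increasing during the chase
  expect_true(all(diff(chase$I + chase$X) <= 1e-6))
})

test_that("integrator settings validate and tolerance defaults follow the formulation", {
  expect_error(solver_settings(abs_tol = 0), "abs_tol")
  expect_error(solver_settings(rel_tol = -1), "rel_tol")
  s_dde <- sfltkin:::resolve_settings(NULL, fix_median)
  expect_equal(c(s_dde$abs_tol, s_dde$rel_tol), c(1e-4, 1e-3))
  p0 <- fix_median
  p0$tau <- 0
  s_ode <- sfltkin:::resolve_settings(NULL, p0)
  expect_equal(c(s_ode$abs_tol, s_ode$rel_tol), c(1e-12, 1e-8))
  expect_error(integrate_model(fix_m1, sflt_params(1, 1, 1, 1), c(0, 0),
                               c(2, 1)), "t_span")
})

test_that("time courses serialize to delimited text and back", {
  tc <- simulate_constitutive(fix_m2, fix_median, duration = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timecourse(tc, path)
  back <- read_timecourse(path)
  expect_equal(back$time_h, tc$time_h)
  expect_equal(back$I, tc$I)
  expect_equal(back$X, tc$X)
  expect_equal(back$phase, tc$phase)
})
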