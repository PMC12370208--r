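# constitutive outputs used by the sensitivity analyses:
# X72h (X at the end of the run), I72h (= I_ss during constitutive
# secretion), and T50_X, the first reported time at which X reaches half of
# the *theoretical* steady state X_ss = (beta/delta) * I_ss.
constitutive_outputs <- function(config, p, duration = 72, settings = NULL) {
  settings <- resolve_settings(settings, p)
  raw <- constitutive_raw(config, p, p, duration, settings)
  X_ss <- steady_state(p)$X_ss
  reached <- which(raw$X >= X_ss / 2)
  c(X72h = raw$X[length(raw$X)],
    I72h = raw$I[length(raw$I)],
    T50_X = if (length(reached)) raw$times[reached[1]] else NA_real_)
}

#' Local univariate sensitivity of constitutive-secretion outputs
#'
#' Each parameter is increased by `delta_frac` (10% by default) in turn,
#' constitutive secretion is re-simulated, and the relative sensitivity
#' `(dO/O) / (dp/p)` is reported for each output: extracellular sFLT1 at
#' the end of the run (`X72h`), intracellular sFLT1 at the end of the run
#' (`I72h`, equal to the steady state during constitutive secretion), and
#' the time for X to reach half its theoretical steady state (`T50_X`).
#' The one-sided discrete definition matches the stated procedure rather
#' than a symmetric derivative.
#'
#' @param config A [model_config()].
#' @param p_base Baseline [sflt_params()] (default: median calibrated set).
#' @param parameters Parameters to perturb.
#' @param delta_frac Fractional increase applied to each parameter.
#' @param duration Constitutive run length, hours.
#' @param settings Optional [solver_settings()].
#' @return A tibble: `parameter`, `output`, `baseline`, `perturbed`,
#'   `sensitivity` (NA with `defined = FALSE` where the baseline output is
#'   zero or undefined).
#' @export
local_sensitivity <- function(config, p_base = sflt_median_params(),
                              parameters = c("alpha", "beta", "gamma",
                                             "delta", "tau"),
                              delta_frac = 0.10, duration = 72,
                              settings = NULL) {
  stopifnot(inherits(config, "sflt_config"), inherits(p_base, "sflt_params"))
  base <- constitutive_outputs(config, p_base, duration, settings)
  rows <- purrr::map(parameters, function(par) {
    p2 <- unclass(p_base)
    p2[[par]] <- p2[[par]] * (1 + delta_frac)
    pert <- constitutive_outputs(config, do.call(sflt_params, p2), duration,
                                 settings)
    defined <- is.finite(base) & base != 0 & is.finite(pert)
    tibble::tibble(parameter = par, output = names(base),
                   baseline = unname(base), perturbed = unname(pert),
                   sensitivity = unname(ifelse(defined,
                                               ((pert - base) / base) /
                                                 delta_frac,
                                               NA_real_)),
                   defined = unname(defined))
  })
  dplyr::bind_rows(rows)
}

#' Global univariate parameter scan of constitutive secretion
#'
#' Multiplies one parameter by log-spaced factors (1e-2 to 1e2 by default)
#' and simulates constitutive secretion at each, tabulating X at the end of
#' the run, the intracellular steady state, and T50_X. Cells where the
#' pre-simulation fails to reach steady state (e.g. extreme maturation
#' delays interacting with the steady-state initialization) are recorded as
#' failed with the error message, and the scan continues.
#'
#' @inheritParams local_sensitivity
#' @param parameter The parameter to scan.
#' @param factors Positive multiplicative factors; default 25 log-spaced
#'   values in `[1e-2, 1e2]`.
#' @return A tibble: `parameter`, `factor`, `value`, `X72h`, `I_ss`,
#'   `T50_X`, `failed`, `message`.
#' @export
global_scan <- function(config, p_base = sflt_median_params(), parameter,
                        factors = NULL, duration = 72, settings = NULL) {
  if (is.null(factors)) factors <- 10 ^ seq(-2, 2, length.out = 25)
  if (any(factors <= 0)) stop("factors must be positive", call. = FALSE)
  rows <- purrr::map(factors, function(f) {
    p2 <- unclass(p_base)
    p2[[parameter]] <- p2[[parameter]] * f
    out <- tryCatch(
      constitutive_outputs(config, do.call(sflt_params, p2), duration,
                           settings),
      error = function(e) e)
    if (inherits(out, "error")) {
      tibble::tibble(parameter = parameter, factor = f,
                     value = p2[[parameter]], X72h = NA_real_,
                     I_ss = NA_real_, T50_X = NA_real_, failed = TRUE,
                     message = conditionMessage(out))
    } else {
      tibble::tibble(parameter = parameter, factor = f,
                     value = p2[[parameter]], X72h = out[["X72h"]],
                     I_ss = out[["I72h"]], T50_X = out[["T50_X"]],
                     failed = FALSE, message = NA_character_)
    }
  })
  dplyr::bind_rows(rows)
}

#' Sensitivity scan over the compound constants
#'
#' Explores the system along and across its constrained manifold: holds one
#' of `c1 = alpha*beta`, `c2 = beta+gamma` fixed while scaling the other,
#' or walks `beta` across `(0, c2]` under both constraints, constructing
#' each parameter set via [parameters_from_beta()] and simulating
#' constitutive secretion.
#'
#' @inheritParams local_sensitivity
#' @param c1,c2 Baseline compound constants.
#' @param delta,tau Reference values for the unconstrained parameters.
#' @param vary `"c1"`, `"c2"` or `"beta"`.
#' @param factors Multiplicative factors for `c1`/`c2` scans.
#' @param beta_frac `beta / c2` held fixed in `c1`/`c2` scans, or the grid
#'   of fractions when `vary = "beta"`.
#' @return A tibble with the scanned value, the constructed parameters and
#'   the constitutive outputs.
#' @export
compound_scan <- function(config, c1, c2, delta, tau = 0,
                          vary = c("c2", "c1", "beta"),
                          factors = 10 ^ seq(-1, 1, length.out = 9),
                          beta_frac = 0.2966, duration = 72,
                          settings = NULL) {
  vary <- match.arg(vary)
  grid <- if (vary == "beta") {
    if (is.null(beta_frac) || length(beta_frac) < 2) {
      beta_frac <- seq(0.1, 1, by = 0.1)
    }
    tibble::tibble(scan = beta_frac, c1 = c1, c2 = c2,
                   beta = beta_frac * c2)
  } else if (vary == "c1") {
    tibble::tibble(scan = factors, c1 = c1 * factors, c2 = c2,
                   beta = beta_frac * c2)
  } else {
    tibble::tibble(scan = factors, c1 = c1, c2 = c2 * factors,
                   beta = beta_frac * c2 * factors)
  }
  rows <- purrr::pmap(grid, function(scan, c1, c2, beta) {
    p <- parameters_from_beta(c1, c2, beta, delta = delta, tau = tau)
    out <- tryCatch(constitutive_outputs(config, p, duration, settings),
                    error = function(e) e)
    failed <- inherits(out, "error")
    tibble::tibble(varied = vary, scan = scan, c1 = c1, c2 = c2,
                   alpha = p$alpha, beta = beta, gamma = p$gamma,
                   X72h = if (failed) NA_real_ else out[["X72h"]],
                   I_ss = if (failed) NA_real_ else out[["I72h"]],
                   T50_X = if (failed) NA_real_ else out[["T50_X"]],
                   failed = failed)
  })
  dplyr::bind_rows(rows)
}
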