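inhibit_params <- function(p, target, fraction) {
  if (!target %in% c("alpha", "beta", "gamma", "delta", "tau")) {
    stop("unknown inhibition target: ", target, call. = FALSE)
  }
  if (fraction < 0 || fraction > 1) {
    stop("fraction inhibition must be in [0, 1]", call. = FALSE)
  }
  p2 <- unclass(p)
  p2[[target]] <- (1 - fraction) * p2[[target]]
  do.call(sflt_params, p2)
}

# readout values (I and X) at the requested times for one inhibition run;
# chemical mode adjusts the parameter at the media change only, genetic
# mode also during the pre-simulation.
inhibition_readouts <- function(config, p_base, target, fraction, mode,
                                readout_times, settings) {
  p_inhib <- inhibit_params(p_base, target, fraction)
  duration <- max(readout_times)
  settings <- resolve_settings(settings, p_base)
  raw <- if (mode == "chemical") {
    constitutive_raw(config, p_base, p_inhib, duration, settings)
  } else {
    constitutive_raw(config, p_inhib, p_inhib, duration, settings)
  }
  idx <- grid_lookup(raw$times, readout_times)
  list(I = pmax(raw$I, 0)[idx], X = pmax(raw$X, 0)[idx], raw = raw)
}

#' Simulate chemical or genetic inhibition of one model process
#'
#' A single rate process is inhibited by fraction `f`, replacing its
#' parameter with `(1 - f) * p`. Chemical (acute) inhibition pre-simulates
#' to steady state with baseline parameters and applies the adjustment
#' together with the media change at `t = 0`; genetic (chronic,
#' siRNA-like) inhibition applies the adjustment throughout, including the
#' pre-simulation, assuming the downregulation is fully effective before
#' the media change. Fold-changes are reported against an uninhibited
#' control that shares everything except `f = 0`.
#'
#' @param config A [model_config()].
#' @param p_base Baseline [sflt_params()].
#' @param target One of `"alpha"`, `"beta"`, `"gamma"`, `"delta"`, `"tau"`.
#' @param fraction Fraction inhibition `f` in `[0, 1]`.
#' @param mode `"chemical"` or `"genetic"`.
#' @param readout_times Hours after media change at which fold-changes are
#'   reported (the run extends to their maximum).
#' @param settings Optional [solver_settings()].
#' @return A list of class `sflt_inhibition`: `timecourse` (perturbed),
#'   `control` (uninhibited) and `fold_changes` (tibble of
#'   perturbed/control ratios per species and readout time).
#' @export
simulate_inhibition <- function(config, p_base = sflt_median_params(),
                                target, fraction,
                                mode = c("chemical", "genetic"),
                                readout_times = c(18, 72),
                                settings = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sflt_config"), inherits(p_base, "sflt_params"))
  duration <- max(readout_times)
  pert <- inhibition_readouts(config, p_base, target, fraction, mode,
                              readout_times, settings)
  ctrl <- inhibition_readouts(config, p_base, target, 0, mode,
                              readout_times, settings)
  set <- resolve_settings(settings, p_base)
  fold <- tibble::tibble(
    species = rep(c("I", "X"), each = length(readout_times)),
    time_h = rep(readout_times, 2),
    perturbed = c(pert$I, pert$X), control = c(ctrl$I, ctrl$X),
    fold_change = c(pert$I / ctrl$I, pert$X / ctrl$X))
  p_inhib <- inhibit_params(p_base, target, fraction)
  tc <- new_timecourse(pert$raw$times, pmax(pert$raw$I, 0),
                       pmax(pert$raw$X, 0), "post_media_change", config,
                       p_inhib, "constitutive", pert$raw$I_ss)
  tc_ctrl <- new_timecourse(ctrl$raw$times, pmax(ctrl$raw$I, 0),
                            pmax(ctrl$raw$X, 0), "post_media_change", config,
                            p_base, "constitutive", ctrl$raw$I_ss)
  structure(list(target = target, fraction = fraction, mode = mode,
                 timecourse = tc, control = tc_ctrl, fold_changes = fold),
            class = "sflt_inhibition")
}

#' @export
print.sflt_inhibition <- function(x, ...) {
  cat("<sflt_inhibition> ", x$mode, " inhibition of ", x$target, " by ",
      round(100 * x$fraction), "%\n", sep = "")
  print(x$fold_changes)
  invisible(x)
}

#' Estimate the fraction inhibition matching an observed fold-change
#'
#' Inverts the inhibition response: finds `f` in `[0, 1]` such that the
#' simulated fold-change of the chosen readout equals the experimentally
#' observed perturbed/control ratio. The response curve is first evaluated
#' on a coarse `f` grid and checked for monotonicity, then the match is
#' found by bisection. Ratios on the wrong side of 1 relative to the
#' response direction are flagged `wrong_direction`; ratios beyond the full
#' inhibition (`f = 1`) response are flagged `exceeds_full_inhibition` —
#' the model cannot achieve the observed strength of impact.
#'
#' @inheritParams simulate_inhibition
#' @param readout_species `"X"` or `"I"`.
#' @param readout_time Hours after media change.
#' @param observed_ratio Observed perturbed/control ratio (> 0).
#' @param f_grid Grid for the feasibility/monotonicity pre-check.
#' @param f_tol Bisection tolerance on `f`.
#' @return A one-row tibble: target, mode, readout, observed ratio,
#'   estimated `fraction` (NA when infeasible) and `feasibility`.
#' @export
estimate_inhibition <- function(config, p_base = sflt_median_params(),
                                target, mode = c("chemical", "genetic"),
                                readout_species = "X", readout_time = 18,
                                observed_ratio,
                                f_grid = seq(0, 1, by = 0.05),
                                f_tol = 1e-4, settings = NULL) {
  mode <- match.arg(mode)
  if (observed_ratio <= 0) stop("observed_ratio must be > 0", call. = FALSE)
  # the f = 0 control run is shared by every response evaluation
  ctrl <- inhibition_readouts(config, p_base, target, 0, mode, readout_time,
                              settings)
  resp <- function(f) {
    r <- inhibition_readouts(config, p_base, target, f, mode, readout_time,
                             settings)
    (if (readout_species == "X") r$X / ctrl$X else r$I / ctrl$I)[1]
  }
  curve <- vapply(f_grid, resp, numeric(1))
  d <- diff(curve)
  tol <- 1e-9 * max(abs(curve))
  if (any(d > tol) && any(d < -tol)) {
    stop("inhibition response is not monotone in f for target ", target,
         "; inspect the response curve", call. = FALSE)
  }
  direction <- sign(curve[length(curve)] - curve[1])
  result <- function(fraction, feasibility) {
    tibble::tibble(target = target, mode = mode,
                   readout_species = readout_species,
                   readout_time = readout_time,
                   observed_ratio = observed_ratio,
                   fraction = fraction, feasibility = feasibility)
  }
  if (abs(observed_ratio - 1) < f_tol) return(result(0, "feasible"))
  if (direction == 0 ||
      sign(observed_ratio - 1) != direction) {
    return(result(NA_real_, "wrong_direction"))
  }
  beyond <- if (direction > 0) observed_ratio > curve[length(curve)]
            else observed_ratio < curve[length(curve)]
  if (beyond) return(result(NA_real_, "exceeds_full_inhibition"))
  # bracket on the grid, then bisect
  cmp <- (curve - observed_ratio) * direction
  hi_idx <- which(cmp >= 0)[1]
  lo <- if (hi_idx == 1) 0 else f_grid[hi_idx - 1]
  hi <- f_grid[hi_idx]
  while (hi - lo > f_tol) {
    mid <- (lo + hi) / 2
    if ((resp(mid) - observed_ratio) * direction >= 0) hi <- mid else lo <- mid
  }
  result((lo + hi) / 2, "feasible")
}

#' Parameter sets spanning the constrained manifold
#'
#' Five parameter sets consistent with the compound constraints, built by
#' setting `beta` to 0.2, 0.4, 0.6, 0.8 and 1.0 times `c2` and solving
#' `alpha = c1/beta`, `gamma = c2 - beta`, with shared `delta` and `tau`.
#' All five reproduce identical extracellular dynamics (which depend on the
#' parameters only through `c1`, `c2`, `delta`) while their intracellular
#' steady states differ five-fold.
#'
#' @param c1,c2 Compound constants.
#' @param delta,tau Shared reference values.
#' @param fractions Multiples of `c2` used for `beta`.
#' @return A tibble with `beta_frac` and the full parameter columns.
#' @export
beta_grid <- function(c1, c2, delta, tau = 0,
                      fractions = c(0.2, 0.4, 0.6, 0.8, 1.0)) {
  rows <- purrr::map(fractions, function(fr) {
    p <- parameters_from_beta(c1, c2, fr * c2, delta = delta, tau = tau)
    dplyr::bind_cols(tibble::tibble(beta_frac = fr),
                     tibble::as_tibble(unclass(p)))
  })
  dplyr::bind_rows(rows)
}

#' Inhibition response curves across base parameter sets
#'
#' Evaluates fold-change versus fraction inhibition for each base parameter
#' set (e.g. the [beta_grid()] sets), readout and mode — the machinery
#' behind comparing observed inhibitor effects with model predictions from
#' different points of the constrained manifold.
#'
#' @inheritParams simulate_inhibition
#' @param base_sets A tibble of parameter sets (columns `alpha`..`kappa`,
#'   optionally `beta_frac` used as the set label).
#' @param readouts A tibble with columns `species` and `time_h`.
#' @param f_grid Fractions of inhibition to evaluate.
#' @return A long tibble: base-set label, `f`, species, time and
#'   `fold_change`.
#' @export
inhibition_response_curves <- function(config, base_sets, target,
                                       mode = c("chemical", "genetic"),
                                       readouts = tibble::tibble(
                                         species = c("X", "I"),
                                         time_h = c(18, 18)),
                                       f_grid = seq(0, 1, by = 0.05),
                                       settings = NULL) {
  mode <- match.arg(mode)
  labels <- if ("beta_frac" %in% names(base_sets)) base_sets$beta_frac
            else seq_len(nrow(base_sets))
  times <- unique(readouts$time_h)
  rows <- purrr::map(seq_len(nrow(base_sets)), function(i) {
    p <- sflt_params(alpha = base_sets$alpha[i], beta = base_sets$beta[i],
                     gamma = base_sets$gamma[i], delta = base_sets$delta[i],
                     tau = base_sets$tau[i],
                     epsilon = base_sets$epsilon[i] %||% 0,
                     kappa = base_sets$kappa[i] %||% 0)
    ctrl <- inhibition_readouts(config, p, target, 0, mode, times, settings)
    purrr::map(f_grid, function(f) {
      r <- inhibition_readouts(config, p, target, f, mode, times, settings)
      purrr::pmap(readouts, function(species, time_h) {
        j <- match(time_h, times)
        fc <- if (species == "X") r$X[j] / ctrl$X[j] else r$I[j] / ctrl$I[j]
        tibble::tibble(base_set = labels[i], f = f, species = species,
                       time_h = time_h, fold_change = fc)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
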