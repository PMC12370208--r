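#' Solver settings for the secretion-model integrator
#'
#' Tolerances default per formulation when left `NULL`: models with a
#' maturation delay integrate with absolute tolerance `1e-4` and relative
#' tolerance `1e-3`; delay-free models use `1e-12` and `1e-8`. The initial
#' step is `1e-2` h. Negative concentrations that emerge from the numerical
#' approximation are clamped to zero at reporting time; clamping a value
#' larger in magnitude than `10 * abs_tol` raises a warning because it
#' indicates solver failure rather than roundoff.
#'
#' @param abs_tol,rel_tol Solver tolerances (> 0), or `NULL` for the
#'   formulation default.
#' @param initial_step Initial step size, hours.
#' @param max_step Maximum step size, hours (steps are additionally capped at
#'   the delay `tau` so delayed arguments always fall in completed history).
#' @param clamp_negative Clamp small negative reported values to zero.
#' @return An object of class `sflt_settings`.
#' @export
solver_settings <- function(abs_tol = NULL, rel_tol = NULL,
                            initial_step = 1e-2, max_step = Inf,
                            clamp_negative = TRUE) {
  if (!is.null(abs_tol) && abs_tol <= 0) stop("abs_tol must be > 0", call. = FALSE)
  if (!is.null(rel_tol) && rel_tol <= 0) stop("rel_tol must be > 0", call. = FALSE)
  if (initial_step <= 0) stop("initial_step must be > 0", call. = FALSE)
  structure(list(abs_tol = abs_tol, rel_tol = rel_tol,
                 initial_step = initial_step, max_step = max_step,
                 clamp_negative = clamp_negative),
            class = "sflt_settings")
}

# resolve NULL tolerances by formulation (delay vs plain ODE)
resolve_settings <- function(settings, p) {
  if (is.null(settings)) settings <- solver_settings()
  dde <- p$tau > 1e-6
  if (is.null(settings$abs_tol)) settings$abs_tol <- if (dde) 1e-4 else 1e-12
  if (is.null(settings$rel_tol)) settings$rel_tol <- if (dde) 1e-3 else 1e-8
  settings
}

params_for_cpp <- function(p) {
  list(alpha = p$alpha, beta = p$beta, gamma = p$gamma, delta = p$delta,
       tau = p$tau, epsilon = p$epsilon, kappa = p$kappa)
}

empty_history <- function() list()

# low-level call; returns the raw C++ result and errors on solver failure
call_integrator <- function(config, p, y0, t0, t1, phase, chase_origin,
                            history, pre_I, disc_origin, settings,
                            report_times) {
  res <- .dde_integrate_cpp(
    t0, t1, as.numeric(y0), params_for_cpp(p),
    config$include_production_decay,
    if (phase == "production_on") 0L else 1L, chase_origin,
    history, pre_I, disc_origin,
    settings$abs_tol, settings$rel_tol, settings$initial_step,
    if (is.finite(settings$max_step)) settings$max_step else -1,
    as.numeric(report_times))
  if (res$status == 1L) {
    stop("integration failure: step size underflow at t = ",
         signif(res$fail_t, 6), " h", call. = FALSE)
  }
  if (res$status == 2L) {
    stop("integration failure: non-finite values at t = ",
         signif(res$fail_t, 6), " h", call. = FALSE)
  }
  res
}

clamp_reported <- function(values, settings) {
  neg <- values < 0
  if (any(neg)) {
    worst <- min(values[neg])
    if (settings$clamp_negative) {
      if (-worst > 10 * settings$abs_tol) {
        warning("clamped a negative value of magnitude ", signif(-worst, 3),
                " exceeding 10 * abs_tol; check solver tolerances",
                call. = FALSE)
      }
      values[neg] <- 0
    }
  }
  values
}

minute_grid <- function(from, to) seq(round(from * 60), round(to * 60)) / 60

new_timecourse <- function(times, I, X, phase, config, p, scenario,
                           pre_history_I = 0) {
  tc <- tibble::tibble(time_h = times, I = I, X = X, phase = phase)
  class(tc) <- c("sflt_timecourse", class(tc))
  attr(tc, "config") <- config
  attr(tc, "params") <- p
  attr(tc, "scenario") <- scenario
  attr(tc, "pre_history_I") <- pre_history_I
  tc
}

#' Integrate the model over a time span (method of steps)
#'
#' Advances the model equations over `t_span` with the delayed term read
#' from the dense history of previously accepted steps; on each
#' sub-interval of length `tau` the delayed argument falls in completed
#' history, so the sub-problem is an ordinary differential equation
#' (the method of steps). Delays below `1e-6` h are integrated on the plain
#' ODE path. The returned history can be passed to a subsequent call so
#' protocols with events (media change, pulse end) restart integration at
#' each discontinuity while keeping the intracellular history continuous.
#'
#' @param config A [model_config()].
#' @param p An [sflt_params()] set.
#' @param y0 Initial state `c(I, X)`.
#' @param t_span Increasing pair of times, hours.
#' @param phase `"production_on"` or `"chase"`.
#' @param chase_origin Time at which the chase began (for production decay).
#' @param history History list from a previous call, or `NULL` for a fresh
#'   run with constant pre-history `pre_history_I`.
#' @param pre_history_I Constant intracellular value assumed before the
#'   first integrated time.
#' @param settings A [solver_settings()].
#' @param report_times Times at which to report the dense solution; defaults
#'   to the whole-minute grid spanning `t_span`.
#' @return A list with elements `timecourse` (tibble `time_h`, `I`, `X`,
#'   `phase`), `state` (named end state), and `history`.
#' @export
integrate_model <- function(config, p, y0, t_span,
                            phase = c("production_on", "chase"),
                            chase_origin = t_span[1], history = NULL,
                            pre_history_I = 0, settings = NULL,
                            report_times = NULL) {
  phase <- match.arg(phase)
  stopifnot(inherits(config, "sflt_config"), inherits(p, "sflt_params"))
  check_params_config(p, config)
  if (length(t_span) != 2 || diff(t_span) <= 0) {
    stop("t_span must be an increasing pair of times", call. = FALSE)
  }
  settings <- resolve_settings(settings, p)
  if (is.null(report_times)) report_times <- minute_grid(t_span[1], t_span[2])
  res <- call_integrator(config, p, y0, t_span[1], t_span[2], phase,
                         chase_origin, history %||% empty_history(),
                         pre_history_I, t_span[1], settings, report_times)
  tc <- new_timecourse(report_times,
                       clamp_reported(res$rep_I, settings),
                       clamp_reported(res$rep_X, settings),
                       phase, config, p, "segment", pre_history_I)
  list(timecourse = tc,
       state = c(I = res$I_end, X = res$X_end, t = res$t_end),
       history = res$history)
}

# raw pre-simulation to intracellular steady state; shared by the protocols
presim_raw <- function(config, p, settings, chunk_h = 20, max_chunks = 200,
                       rel_change = 0.005, floor = 1e-6) {
  if (p$beta + p$gamma <= 0) {
    stop("pre-simulation requires beta + gamma > 0", call. = FALSE)
  }
  history <- empty_history()
  state <- c(0, 0)
  t <- 0
  for (chunk in seq_len(max_chunks)) {
    I_start <- state[1]
    res <- call_integrator(config, p, state, t, t + chunk_h,
                           "production_on", 0, history, 0, 0, settings,
                           numeric(0))
    history <- res$history
    state <- c(res$I_end, res$X_end)
    t <- res$t_end
    if (abs(state[1] - I_start) / max(I_start, floor) < rel_change) {
      return(list(I = state[1], X = state[2], t = t, chunks = chunk))
    }
  }
  stop("pre-simulation did not reach steady state within ", max_chunks,
       " chunks of ", chunk_h, " h", call. = FALSE)
}

#' Run the system to its constitutive steady state
#'
#' Starting from `(I, X) = (0, 0)` with zero pre-history, integrates in 20 h
#' chunks until the intracellular pool changes by less than 0.5% over a
#' chunk (with a floor of `1e-6` #/cell in the denominator so a
#' production-free system converges immediately).
#'
#' @inheritParams integrate_model
#' @param chunk_h Chunk length, hours.
#' @param max_chunks Chunk cap before a non-convergence error.
#' @return A list with `I`, `X`, `t` (elapsed hours) and `chunks`.
#' @export
run_to_steady_state <- function(config, p, settings = NULL, chunk_h = 20,
                                max_chunks = 200) {
  stopifnot(inherits(config, "sflt_config"), inherits(p, "sflt_params"))
  check_params_config(p, config)
  settings <- resolve_settings(settings, p)
  presim_raw(config, p, settings, chunk_h = chunk_h, max_chunks = max_chunks)
}

# internal: constitutive protocol with possibly different pre-simulation and
# main-phase parameter sets (chemical inhibition changes them at t = 0)
constitutive_raw <- function(config, p_presim, p_main, duration, settings) {
  pre <- presim_raw(config, p_presim, settings)
  grid <- minute_grid(0, duration)
  res <- call_integrator(config, p_main, c(pre$I, 0), 0, duration,
                         "production_on", 0, empty_history(), pre$I, 0,
                         settings, grid)
  list(times = grid, I = res$rep_I, X = res$rep_X, I_ss = pre$I,
       end = c(res$I_end, res$X_end))
}

#' Simulate a constitutive secretion experiment
#'
#' Pre-simulates to intracellular steady state, then applies a media change
#' at `t = 0` — the extracellular pool is reset to zero while the
#' intracellular pool and its history (constant at the steady state) are
#' carried over — and integrates for `duration` hours, reporting at
#' 1-minute intervals.
#'
#' @inheritParams integrate_model
#' @param duration Simulated hours after the media change (24 or 72 in the
#'   emulated experiments).
#' @return An `sflt_timecourse` tibble (`time_h`, `I`, `X`, `phase`).
#' @examples
#' tc <- simulate_constitutive(model_config("M2"), sflt_median_params(),
#'                             duration = 24)
#' tail(tc)
#' @export
simulate_constitutive <- function(config, p, duration = 24, settings = NULL) {
  stopifnot(inherits(config, "sflt_config"), inherits(p, "sflt_params"))
  check_params_config(p, config)
  settings <- resolve_settings(settings, p)
  raw <- constitutive_raw(config, p, p, duration, settings)
  new_timecourse(raw$times,
                 clamp_reported(raw$I, settings),
                 clamp_reported(raw$X, settings),
                 "post_media_change", config, p, "constitutive",
                 pre_history_I = raw$I_ss)
}

# internal pulse-chase protocol returning bare vectors
pulse_chase_raw <- function(config, p, settings, pulse_h = 1 / 3,
                            chase_h = 10) {
  pulse_grid <- minute_grid(-pulse_h, 0)
  res_pulse <- call_integrator(config, p, c(0, 0), -pulse_h, 0,
                               "production_on", 0, empty_history(), 0,
                               -pulse_h, settings, pulse_grid)
  chase_grid <- minute_grid(0, chase_h)
  res_chase <- call_integrator(config, p, c(res_pulse$I_end, 0), 0, chase_h,
                               "chase", 0, res_pulse$history, 0, 0, settings,
                               chase_grid)
  n_pulse <- length(pulse_grid) - 1L  # drop duplicate t = 0 (chase owns it)
  list(times = c(pulse_grid[seq_len(n_pulse)], chase_grid),
       I = c(res_pulse$rep_I[seq_len(n_pulse)], res_chase$rep_I),
       X = c(res_pulse$rep_X[seq_len(n_pulse)], res_chase$rep_X),
       phase = c(rep("pulse", n_pulse),
                 rep("chase", length(chase_grid))),
       pulse_end = c(res_pulse$I_end, res_pulse$X_end))
}

#' Simulate a pulse-chase secretion experiment
#'
#' A 20-minute labeling pulse from `(0, 0)` with production on (only the
#' labeled cohort is tracked, so the system starts empty), then a media
#' change at `t = 0` that zeroes the extracellular pool while keeping the
#' intracellular pool and its history, followed by a 10-hour chase with
#' production off — or decaying as `alpha * exp(-kappa t)` when the model
#' includes production decay. Reported at 1-minute intervals; chase times
#' are `t >= 0`, pulse times negative.
#'
#' @inheritParams integrate_model
#' @param chase_h Chase duration, hours.
#' @return An `sflt_timecourse` tibble (`time_h`, `I`, `X`, `phase`).
#' @export
simulate_pulse_chase <- function(config, p, settings = NULL, chase_h = 10) {
  stopifnot(inherits(config, "sflt_config"), inherits(p, "sflt_params"))
  check_params_config(p, config)
  settings <- resolve_settings(settings, p)
  raw <- pulse_chase_raw(config, p, settings, chase_h = chase_h)
  new_timecourse(raw$times,
                 clamp_reported(raw$I, settings),
                 clamp_reported(raw$X, settings),
                 raw$phase, config, p, "pulse_chase", pre_history_I = 0)
}

#' Dispatch a scenario simulation
#'
#' @inheritParams integrate_model
#' @param scenario `"constitutive"` or `"pulse_chase"`.
#' @param duration Duration for the constitutive scenario, hours.
#' @return An `sflt_timecourse`.
#' @export
simulate_scenario <- function(config, p, scenario, duration = 24,
                              settings = NULL) {
  switch(scenario,
         constitutive = simulate_constitutive(config, p, duration, settings),
         pulse_chase = simulate_pulse_chase(config, p, settings),
         stop("unknown scenario: ", scenario, call. = FALSE))
}

#' Write or read a time course as delimited text
#'
#' Tab-separated columns `time_h`, `I`, `X`, `phase`.
#'
#' @param tc An `sflt_timecourse` (or any tibble with those columns).
#' @param path File path.
#' @export
write_timecourse <- function(tc, path) {
  readr::write_tsv(tc[, c("time_h", "I", "X", "phase")], path)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    time_h = readr::col_double(), I = readr::col_double(),
    X = readr::col_double(), phase = readr::col_character()))
}
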