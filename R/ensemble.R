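#' Summary statistics of a filtered fit ensemble
#'
#' For each core parameter and for the compound constants `c1 = alpha*beta`
#' and `c2 = beta+gamma`, computes mean, SD, CV (= SD/mean), median, MAD,
#' IQR, both ratio conventions (median/IQR and IQR/median), min and max.
#' The MAD is the raw median absolute deviation (no normal-consistency
#' factor) and quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), so the summaries are reproducible from the
#' serialized ensemble.
#'
#' @param fits A (typically cost-filtered) `sflt_fits` tibble.
#' @return A tibble with one row per quantity and one column per statistic.
#' @export
summarize_ensemble <- function(fits) {
  if (nrow(fits) == 0) stop("empty ensemble", call. = FALSE)
  config <- attr(fits, "config")
  pars <- if (!is.null(config)) free_param_names(config)
          else c("alpha", "beta", "gamma", "delta", "tau")
  cols <- c(stats::setNames(as.list(fits[pars]), pars),
            list(c1 = fits$alpha * fits$beta,
                 c2 = fits$beta + fits$gamma))
  rows <- purrr::imap(cols, function(x, nm) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    med <- q[2]
    tibble::tibble(
      quantity = nm, mean = mean(x), sd = stats::sd(x),
      cv = stats::sd(x) / mean(x), median = med,
      mad = stats::median(abs(x - med)), iqr = iqr,
      median_over_iqr = med / iqr, iqr_over_median = iqr / med,
      min = min(x), max = max(x))
  })
  dplyr::bind_rows(rows)
}

#' Theoretical bounds implied by the compound constraints
#'
#' With `c1 = alpha*beta` and `c2 = beta+gamma` fixed, the admissible
#' parameter sets satisfy `beta, gamma in (0, c2]`, `alpha >= c1/c2`, and
#' the intracellular steady state `I_ss = c1/(beta*c2)` is bounded below by
#' `c1/c2^2` (attained at `beta = c2`).
#'
#' @param c1,c2 Compound constants (> 0).
#' @return A one-row tibble: `min_I_ss`, `min_alpha`, `max_beta`,
#'   `max_gamma`.
#' @export
steady_state_bounds <- function(c1, c2) {
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be positive", call. = FALSE)
  tibble::tibble(min_I_ss = c1 / c2 ^ 2, min_alpha = c1 / c2,
                 max_beta = c2, max_gamma = c2)
}

#' Process fluxes along a simulated trajectory
#'
#' The rate of molecules traversing each edge of the reaction network:
#' production `Phi(Prod)` (`alpha`, or the decaying chase term), secretion
#' `Phi(Secr) = beta * I(t - tau)`, intracellular degradation
#' `Phi(IDeg) = gamma * I(t - tau)` and extracellular degradation
#' `Phi(XDeg) = delta * X(t)`. The delayed intracellular amount is read
#' from the stored trajectory (linear interpolation on the 1-minute grid),
#' falling back to the trajectory's constant pre-history before its first
#' reported time.
#'
#' @param tc An `sflt_timecourse`.
#' @param p The [sflt_params()] used to produce it (defaults to the
#'   trajectory's own attribute).
#' @return A tibble: `time_h`, `phase`, `prod`, `secretion`,
#'   `intracellular_degradation`, `extracellular_degradation`.
#' @export
compute_fluxes <- function(tc, p = attr(tc, "params")) {
  if (is.null(p)) stop("supply the parameter set used for the trajectory",
                       call. = FALSE)
  config <- attr(tc, "config") %||% model_config(
    include_delay = p$tau > 0, include_internalization = p$epsilon > 0,
    include_production_decay = p$kappa > 0)
  pre_I <- attr(tc, "pre_history_I") %||% tc$I[1]
  t_delayed <- tc$time_h - p$tau
  if (p$tau > 0) {
    delayed_I <- stats::approx(tc$time_h, tc$I, xout = t_delayed,
                               rule = 2)$y
    delayed_I[t_delayed < min(tc$time_h)] <- pre_I
  } else {
    delayed_I <- tc$I
  }
  chase <- tc$phase == "chase"
  prod <- ifelse(chase,
                 if (config$include_production_decay)
                   p$alpha * exp(-p$kappa * pmax(tc$time_h, 0)) else 0,
                 p$alpha)
  tibble::tibble(
    time_h = tc$time_h, phase = tc$phase, prod = prod,
    secretion = p$beta * delayed_I,
    intracellular_degradation = p$gamma * delayed_I,
    extracellular_degradation = p$delta * tc$X)
}
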