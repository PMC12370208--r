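#' Evaluate the model right-hand side at one state
#'
#' The instantaneous rates of change of intracellular (`I`) and extracellular
#' (`X`) sFLT1:
#' \deqn{dI/dt = production - \beta I(t-\tau) - \gamma I(t-\tau) + \epsilon X}
#' \deqn{dX/dt = \beta I(t-\tau) - \delta X - \epsilon X}
#' where production is `alpha` while synthesis is on and, during the chase
#' phase of a pulse-chase experiment, either 0 (no production-decay process)
#' or `alpha * exp(-kappa * t_since_chase)`. For models without a maturation
#' delay the delayed intracellular amount equals the current one.
#'
#' This scalar form is the reference definition of the dynamics; the
#' integrator evaluates the identical expressions in compiled code.
#'
#' @param config A [model_config()].
#' @param p An [sflt_params()] set (zeros for absent processes).
#' @param I,X Current intracellular and extracellular amounts (#/cell).
#' @param delayed_I Intracellular amount at `t - tau`; must equal `I` when
#'   the model has no delay.
#' @param phase `"production_on"` or `"chase"`.
#' @param t_since_chase Hours since the chase began (used only in the chase
#'   phase).
#' @return A tibble with columns `dI_dt` and `dX_dt` (#/cell/h).
#' @examples
#' m1 <- model_config("M1")
#' p <- sflt_params(100, 0.1, 0.1, 0.05)
#' secretion_rhs(m1, p, I = 1000, X = 0, delayed_I = 1000)
#' @export
secretion_rhs <- function(config, p, I, X, delayed_I = I,
                          phase = c("production_on", "chase"),
                          t_since_chase = 0) {
  phase <- match.arg(phase)
  stopifnot(inherits(config, "sflt_config"), inherits(p, "sflt_params"))
  check_params_config(p, config)
  if (any(c(I, X, delayed_I) < 0)) {
    stop("states must be non-negative", call. = FALSE)
  }
  if (phase == "chase" && t_since_chase < 0) {
    stop("t_since_chase must be >= 0 in the chase phase", call. = FALSE)
  }
  if (!config$include_delay && !isTRUE(all.equal(delayed_I, I))) {
    stop("delayed_I must equal I for models without a maturation delay",
         call. = FALSE)
  }
  production <- if (phase == "production_on") {
    p$alpha
  } else if (config$include_production_decay) {
    p$alpha * exp(-p$kappa * t_since_chase)
  } else {
    0
  }
  tibble::tibble(
    dI_dt = production - p$beta * delayed_I - p$gamma * delayed_I +
      p$epsilon * X,
    dX_dt = p$beta * delayed_I - p$delta * X - p$epsilon * X
  )
}
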