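#' Plot a simulated secretion time course
#'
#' Intracellular and extracellular sFLT1 over time, faceted by species,
#' with the pulse window shaded for pulse-chase trajectories.
#'
#' @param object An `sflt_timecourse`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sflt_timecourse
#' @export
autoplot.sflt_timecourse <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("time_h", "I", "X", "phase")],
    cols = c("I", "X"), names_to = "species", values_to = "amount")
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h,
                                           y = .data$amount)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::facet_wrap(~species, scales = "free_y",
                        labeller = ggplot2::labeller(species = c(
                          I = "intracellular (I)",
                          X = "extracellular (X)"))) +
    ggplot2::labs(x = "time after media change (h)",
                  y = "sFLT1 (#/cell)") +
    ggplot2::theme_minimal()
  if (any(object$phase == "pulse")) {
    gg <- gg + ggplot2::annotate("rect", xmin = min(object$time_h), xmax = 0,
                                 ymin = -Inf, ymax = Inf, alpha = 0.12,
                                 fill = "grey40")
  }
  gg
}

#' Plot a multistart cost distribution
#'
#' Cost per optimization run on a log axis, with the 10%-above-minimum
#' filter threshold marked.
#'
#' @param object An `sflt_fits` tibble.
#' @param tolerance Filter fraction to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sflt_fits
#' @export
autoplot.sflt_fits <- function(object, tolerance = 0.10, ...) {
  conv <- object[object$converged & is.finite(object$cost), ]
  thr <- (1 + tolerance) * min(conv$cost)
  ggplot2::ggplot(conv, ggplot2::aes(x = .data$cost)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::geom_vline(xintercept = thr, color = "#b2182b",
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cost (sum of squared residuals)", y = "runs") +
    ggplot2::theme_minimal()
}

#' Tile plot of local relative sensitivities
#'
#' @param sens Output of [local_sensitivity()].
#' @return A ggplot object.
#' @export
plot_local_sensitivity <- function(sens) {
  ggplot2::ggplot(sens, ggplot2::aes(x = .data$output, y = .data$parameter,
                                     fill = .data$sensitivity)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$sensitivity), "n.d.",
                     sprintf("%.2f", .data$sensitivity))), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::labs(x = "output", y = "parameter",
                  fill = "relative\nsensitivity") +
    ggplot2::theme_minimal()
}

#' Plot inhibition response curves
#'
#' Fold-change at the readout versus fraction inhibition, one line per base
#' parameter set.
#'
#' @param curves Output of [inhibition_response_curves()].
#' @return A ggplot object.
#' @export
plot_response_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$f, y = .data$fold_change,
                                       color = factor(.data$base_set))) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(species ~ time_h,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "fraction inhibition f",
                  y = "fold-change vs control", color = "base set\n(beta/c2)") +
    ggplot2::theme_minimal()
}
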