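#' Press raster with prototypical boundaries
#'
#' One row per participant, a tick per press, with the prototypical
#' boundaries overlaid as vertical lines.
#'
#' @param presses Press tibble (`participant_id`, `time_s`).
#' @param proto Optional prototypical boundary tibble (`time_s`) or numeric
#'   vector of boundary times.
#' @return A ggplot object.
#' @export
plot_press_raster <- function(presses, proto = NULL) {
  p <- ggplot2::ggplot(presses,
                       ggplot2::aes(x = .data$time_s, y = .data$participant_id)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Boundary presses by participant") +
    ggplot2::theme_minimal()
  if (!is.null(proto)) {
    times <- if (is.data.frame(proto)) proto$time_s else as.numeric(proto)
    p <- p + ggplot2::geom_vline(xintercept = times, colour = "red",
                                 alpha = 0.4, linewidth = 0.3)
  }
  p
}

#' Plot a lag curve
#'
#' Lagged correlation against lag, with the peak latency marked. A positive
#' peak means the participant's responses follow the prototypical
#' boundaries.
#'
#' @param object An `eventseg_lag_curve` tibble from [lag_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eventseg_lag_curve <- function(object, ...) {
  peak <- peak_latency(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_s, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = peak, colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "lag (s); positive = responses follow prototypical boundaries",
                  y = "Pearson r",
                  title = sprintf("Lagged correlation (peak at %.1f s)", peak)) +
    ggplot2::theme_minimal()
}

#' Diagnostic scatter plots for the battery
#'
#' ASRS total against the main segmentation and memory outcomes, with linear
#' trends, mirroring the study's correlational figures.
#'
#' @param object A `seg_battery` object from [run_battery()].
#' @param ... Unused.
#' @return A ggplot object (facetted scatter grid).
#' @export
autoplot.seg_battery <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$data[, c("total", "n_presses", "acc_within", "acc_across",
                    "jaccard", "agreement")],
    cols = -"total", names_to = "outcome", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$total, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "red", linewidth = 0.5) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = "ASRS total score", y = NULL,
                  title = "ASRS score vs segmentation and memory outcomes") +
    ggplot2::theme_minimal()
}

#' Memory accuracy by condition
#'
#' Cohort mean accuracy for the within-scene and across-scenes conditions
#' with 95% confidence intervals.
#'
#' @param scores Output of [score_memory()].
#' @return A ggplot object.
#' @export
plot_memory_accuracy <- function(scores) {
  s <- memory_condition_summary(scores)
  s$ci <- qt(0.975, s$n - 1) * s$se
  ggplot2::ggplot(s, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey40", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$ci,
                                        ymax = .data$mean + .data$ci),
                           width = 0.15) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "temporal-order accuracy",
                  title = "Temporal-order memory by condition") +
    ggplot2::theme_minimal()
}
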