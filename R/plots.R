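#' Plot a recording with optional event overlays
#'
#' Draws both channels (downsampled for display) with detected or true
#' event intervals shaded.
#'
#' @param object An `eeg_recording`.
#' @param events Optional tibble of intervals (`onset_s`, `offset_s`).
#' @param max_points Display resolution cap per channel. Default 20000.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_recording <- function(object, events = NULL, max_points = 20000,
                                   ...) {
  step <- max(1L, floor(nrow(object) / max_points))
  df <- tibble::as_tibble(object)[seq(1, nrow(object), by = step), ]
  long <- tidyr::pivot_longer(df, dplyr::any_of(c("CA3_uV", "MCX_uV")),
                              names_to = "channel", values_to = "uV")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$uV)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "amplitude (uV)")
  if (!is.null(events) && nrow(tibble::as_tibble(events)) > 0) {
    iv <- tibble::as_tibble(events)
    p <- p + ggplot2::geom_rect(
      data = iv,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "red",
      inherit.aes = FALSE)
  }
  p
}

#' Plot a threshold-calibration sweep
#'
#' Sensitivity and specificity as a function of the threshold constant C,
#' with the calibration criterion and the chosen C marked.
#'
#' @param calibration A [calibrate_threshold()] result.
#' @return A ggplot object.
#' @export
plot_calibration <- function(calibration) {
  sw <- tidyr::pivot_longer(
    calibration$sweep[, c("C", "sensitivity", "specificity")],
    c("sensitivity", "specificity"),
    names_to = "measure", values_to = "value")
  ggplot2::ggplot(sw, ggplot2::aes(x = .data$C, y = .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = calibration$criterion, linetype = 2) +
    ggplot2::geom_vline(xintercept = calibration$chosen_C, linetype = 3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "threshold constant C", y = NULL,
                  title = sprintf("chosen C = %g", calibration$chosen_C))
}

#' @rdname plot_calibration
#' @param object A `spike_calibration`.
#' @param ... Unused.
#' @export
autoplot.spike_calibration <- function(object, ...) plot_calibration(object)

#' Plot a group-by-day metric summary
#'
#' Mean with SEM error bars per day, coloured by group, for one metric of
#' an [aggregate_day_metrics()] summary.
#'
#' @param summary A `group_summary` tibble.
#' @param metric Metric name to display (default first present).
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summary, metric = NULL) {
  s <- tibble::as_tibble(summary)
  metric <- metric %||% s$metric[1]
  s <- s[s$metric == metric, ]
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$day), y = .data$mean,
                                  colour = .data$group, group = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      width = 0.2, position = ggplot2::position_dodge(0.3)) +
    ggplot2::labs(x = "injection day", y = metric)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
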