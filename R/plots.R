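#' Plot a simulated trajectory
#'
#' Four stacked panels: eye and target position, eye velocity, motor
#' command, and the position-feedback Kalman weight `k_pos`.
#'
#' @param object A `sacc_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sacc_trajectory <- function(object, ...) {
  long <- object |>
    dplyr::transmute(
      time = .data$time,
      `position (deg)` = .data$eye_pos,
      `target (deg)` = .data$target_pos,
      `velocity (deg/s)` = .data$eye_vel,
      `command u` = .data$u,
      `sensory weight k_pos` = .data$k_pos
    ) |>
    tidyr::pivot_longer(-"time", names_to = "signal")
  panel <- c(
    "position (deg)" = "position", "target (deg)" = "position",
    "velocity (deg/s)" = "velocity", "command u" = "command",
    "sensory weight k_pos" = "sensory weight"
  )
  long$panel <- factor(panel[long$signal], levels = unique(panel))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the sensory weight with the suppression window shaded
#'
#' @param traj A `sacc_trajectory`.
#' @param report Optional [suppression_window()] result (computed if
#'   missing).
#' @return A ggplot object: `k_pos` over time, baseline as a dashed line,
#'   the suppression window shaded, saccade onset marked.
#' @export
plot_suppression <- function(traj, report = NULL) {
  if (is.null(report)) report <- suppression_window(traj)
  p <- ggplot2::ggplot(traj, ggplot2::aes(.data$time, .data$k_pos)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = "position feedback weight") +
    ggplot2::theme_minimal()
  if (isTRUE(report$suppressed)) {
    onset <- report$saccade$onset
    p <- p +
      ggplot2::annotate("rect",
        xmin = onset + report$onset_timelocked,
        xmax = onset + report$offset_timelocked,
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey40"
      ) +
      ggplot2::geom_hline(yintercept = report$baseline_gain,
                          linetype = "dashed", linewidth = 0.3) +
      ggplot2::geom_vline(xintercept = onset, linetype = "dotted",
                          linewidth = 0.3)
  }
  p
}
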