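# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline geom_vline
#'   geom_boxplot facet_grid facet_wrap labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a simulated trial
#'
#' Shows the vertical marker trajectories with the ground-truth events
#' (heel strikes on the calcaneus traces, toe-offs on the metatarsal traces).
#'
#' @param object A `gait_trial`.
#' @param window Optional time window (length-2, seconds) to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_trial <- function(object, window = c(10, 20), ...) {
  mk <- object$markers %>%
    filter(.data$t >= window[1], .data$t <= window[2]) %>%
    tidyr::pivot_longer(-"t", names_to = "channel", values_to = "z") %>%
    mutate(side = ifelse(grepl("_L_", .data$channel), "L", "R"),
           marker = ifelse(grepl("calc", .data$channel), "calcaneus",
                           "metatarsal"))
  ev <- object$events %>%
    filter(.data$time >= window[1], .data$time <= window[2]) %>%
    mutate(marker = ifelse(.data$type == "HS", "calcaneus", "metatarsal"))
  ggplot(mk, aes(x = .data$t, y = .data$z)) +
    geom_line() +
    geom_vline(data = ev, aes(xintercept = .data$time, colour = .data$type),
               linetype = "dashed", alpha = 0.6) +
    facet_grid(marker ~ side, scales = "free_y") +
    labs(x = "time (s)", y = "vertical position (mm)",
         colour = "event",
         title = sprintf("%s | %.2f m/s | %s", object$subject, object$speed,
                         object$placement)) +
    theme_minimal()
}

#' Bland-Altman plot
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  pts <- attr(object, "points")
  ggplot(pts, aes(x = .data$mean, y = .data$diff)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = object$bias) +
    geom_hline(yintercept = c(object$loa_low, object$loa_high),
               linetype = "dashed") +
    labs(x = "mean of M1 and M2 (s)", y = "M1 - M2 (s)",
         title = sprintf("bias %.3f s, LoA [%.3f, %.3f] s",
                         object$bias, object$loa_low, object$loa_high)) +
    theme_minimal()
}

#' Agreement report overview plot
#'
#' Per-condition rRMSE medians by parameter, speed and placement.
#'
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_report <- function(object, ...) {
  ggplot(object$rrmse_table,
         aes(x = factor(.data$speed), y = .data$median,
             colour = .data$placement, group = .data$placement)) +
    geom_point() + geom_line() +
    facet_wrap(~ .data$parameter, scales = "free_y") +
    labs(x = "speed (m/s)", y = "median rRMSE (%)", colour = "placement") +
    theme_minimal()
}

#' Training-curve plot for a detector
#'
#' @param object A `gait_detector`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_detector <- function(object, ...) {
  ggplot(object$report, aes(x = .data$epoch, y = .data$loss)) +
    geom_line() + geom_point() +
    labs(x = "epoch", y = "weighted BCE loss",
         title = sprintf("stream %s", object$stream)) +
    theme_minimal()
}
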