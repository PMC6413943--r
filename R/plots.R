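#' Presence-absence tile plot
#'
#' The classic telemetry presence chart: one row per tag, one tile per day
#' the animal was detected.
#'
#' @param detections Canonical detection tibble.
#' @param tags Tag deployment tibble.
#' @param utc_offset_hours Local-day offset.
#' @param season_align Use a July-1st-aligned day-of-season axis.
#' @return A ggplot.
#' @export
plot_presence <- function(detections, tags, utc_offset_hours = -6,
                          season_align = FALSE) {
  long <- daily_presence_matrix(detections, tags, utc_offset_hours,
                                season_align = season_align, long = TRUE)
  xvar <- if (season_align) "season_day" else "date"
  ggplot2::ggplot(long[long$present == 1, ],
                  ggplot2::aes(x = .data[[xvar]], y = .data$tag_id)) +
    ggplot2::geom_tile(fill = "grey20") +
    ggplot2::labs(x = if (season_align) "day of season (from 1 July)" else NULL,
                  y = NULL, title = "Daily presence at the array") +
    ggplot2::theme_minimal()
}

#' Hour-of-day detection rose
#'
#' @param detections Canonical detection tibble.
#' @param utc_offset_hours Local-time offset.
#' @return A ggplot (polar histogram of detections by hour of day).
#' @export
plot_diel <- function(detections, utc_offset_hours = -6) {
  prof <- hour_profile(detections, utc_offset_hours)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$hour_of_day, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "steelblue", colour = "white") +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(breaks = seq(0, 21, 3), limits = c(-0.5, 23.5)) +
    ggplot2::labs(x = NULL, y = "detections",
                  title = "Diel timing of detections") +
    ggplot2::theme_minimal()
}

#' Periodogram plot
#'
#' @param spectrum Spectrum tibble from [periodogram_peak()].
#' @param max_period_h Truncate the period axis (default 72 h).
#' @return A ggplot of power against period.
#' @export
plot_periodogram <- function(spectrum, max_period_h = 72) {
  sp <- spectrum[spectrum$period_h <= max_period_h, ]
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$period_h, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 24, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "period (h)", y = "spectral power",
                  title = "Detection periodogram") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a mixed-model fit
#'
#' @param object An `lmm_fit`.
#' @param ... Unused.
#' @return A ggplot of fixed effects with 95% intervals.
#' @export
autoplot.lmm_fit <- function(object, ...) {
  td <- tidy(object, effects = "fixed")
  crit <- ifelse(is.na(td$df), stats::qnorm(0.975), qt(0.975, td$df))
  td$lo <- td$estimate - crit * td$std.error
  td$hi <- td$estimate + crit * td$std.error
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "estimate (log hours)", y = NULL,
                  title = "Site effects on visit duration") +
    ggplot2::theme_minimal()
}
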