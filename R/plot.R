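#' Plot a rendered trace
#'
#' Facets the analog, TTL and mask lines of a trace over time. Digital
#' lines are drawn as 0/1 steps.
#'
#' @param object A `laser_trace` tibble (from [render_channel()] or a
#'   [run_device()] result's `$trace`).
#' @param channels Optional character vector of column names to show
#'   (default: all non-time columns).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot laser_trace
#' @export
autoplot.laser_trace <- function(object, channels = NULL, ...) {
  df <- as_tibble(object)
  if (is.null(channels)) channels <- setdiff(names(df), "t_s")
  long <- df |>
    dplyr::select(dplyr::all_of(c("t_s", channels))) |>
    dplyr::mutate(dplyr::across(-"t_s", as.numeric)) |>
    tidyr::pivot_longer(-"t_s", names_to = "line", values_to = "value") |>
    dplyr::mutate(line = factor(.data$line, levels = channels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$value)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$line), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot pulse-train timing histograms
#'
#' Histograms of per-pulse duration and onset-to-onset interval, the two
#' panels used to validate train timing.
#'
#' @param object A [pulse_stats()] object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pulse_stats
#' @export
autoplot.pulse_stats <- function(object, bins = 30, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("duration_ms", "interval_ms"),
                        names_to = "metric", values_to = "ms") |>
    dplyr::filter(!is.na(.data$ms))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ms)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free") +
    ggplot2::labs(x = "ms", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot the phase-offset distribution
#'
#' Histogram of the per-sample phase differences with the circular mean
#' marked.
#'
#' @param object A [phase_difference_stats()] object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phase_stats
#' @export
autoplot.phase_stats <- function(object, bins = 60, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase_diff_rad)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::geom_vline(xintercept = object$circ_mean_rad,
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "phase difference (rad)", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve
#'
#' Measured optical power against control fraction with the fitted line.
#'
#' @param object A [calib_fit()] curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  df <- tibble(fraction = object$steps, mW = object$measured_mW)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$mW)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "red") +
    ggplot2::labs(x = "control fraction", y = "measured power (mW)",
                  title = sprintf("laser %d (r2 = %.4f)",
                                  object$laser_id, object$r2)) +
    ggplot2::theme_minimal()
}
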