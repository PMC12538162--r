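#' Detect pulse onsets and offsets by threshold crossing
#'
#' Finds rising and falling crossings of a threshold set at a fraction of
#' the channel's maximum (default half-maximum), refining each crossing
#' time by linear interpolation between the two bracketing samples.
#' Crossings are paired into (onset, offset) pulses. A channel that starts
#' HIGH contributes an onset at the first sample and one ending HIGH an
#' offset at the last sample (boundary-truncated pulses are kept, not
#' silently dropped). A flat channel yields an empty result.
#'
#' @param trace A trace tibble with a `t_s` column (seconds, uniform).
#' @param channel Column to analyse (unquoted name or string). Logical
#'   TTL/mask columns are treated as 0/1.
#' @param threshold_fraction Threshold as a fraction of the channel
#'   maximum, default 0.5.
#' @return A tibble with columns `onset_ms`, `offset_ms`, `duration_ms`,
#'   one row per detected pulse, onsets strictly increasing.
#' @export
detect_edges <- function(trace, channel, threshold_fraction = 0.5) {
  x <- as.numeric(pull_channel(trace, {{ channel }}))
  t_ms <- trace$t_s * 1000
  mx <- max(x)
  if (!is.finite(mx) || mx <= 0) {
    return(tibble(onset_ms = numeric(), offset_ms = numeric(),
                  duration_ms = numeric()))
  }
  thr <- threshold_fraction * mx
  above <- x >= thr
  n <- length(x)
  rising <- which(!above[-n] & above[-1])       # crossing in (i, i+1]
  falling <- which(above[-n] & !above[-1])
  interp <- function(i) {
    t_ms[i] + (thr - x[i]) / (x[i + 1] - x[i]) * (t_ms[i + 1] - t_ms[i])
  }
  onsets <- if (length(rising)) vapply(rising, interp, 1) else numeric()
  offsets <- if (length(falling)) vapply(falling, interp, 1) else numeric()
  if (above[1]) onsets <- c(t_ms[1], onsets)
  if (above[n]) offsets <- c(offsets, t_ms[n])
  m <- min(length(onsets), length(offsets))
  onsets <- onsets[seq_len(m)]
  offsets <- offsets[seq_len(m)]
  tibble(onset_ms = onsets, offset_ms = offsets,
         duration_ms = offsets - onsets)
}

pull_channel <- function(trace, channel) {
  q <- enquo(channel)
  nm <- tryCatch(as_name(q), error = function(e) NULL)
  if (!is.null(nm) && nm %in% names(trace)) return(trace[[nm]])
  dplyr::pull(trace, {{ channel }})
}

#' Pulse-train timing statistics
#'
#' Summarises a pulsatile channel: onset and offset times, per-pulse
#' durations, onset-to-onset intervals (the interpulse duration -- its
#' mean is the reciprocal of the train frequency) and the frequency
#' estimate `1000 / mean(interval)`.
#'
#' @inheritParams detect_edges
#' @return An object of class `pulse_stats`; see [tidy.pulse_stats()] for
#'   the per-pulse table and [glance.pulse_stats()] for the one-row
#'   summary.
#' @export
pulse_stats <- function(trace, channel, threshold_fraction = 0.5) {
  edges <- detect_edges(trace, {{ channel }}, threshold_fraction)
  if (nrow(edges) < 2) {
    abort("need at least 2 pulses for timing statistics.",
          class = "optopulse_analysis_error")
  }
  intervals <- diff(edges$onset_ms)
  structure(list(onsets_ms = edges$onset_ms, offsets_ms = edges$offset_ms,
                 durations_ms = edges$duration_ms,
                 onset_intervals_ms = intervals,
                 freq_hz_est = 1000 / mean(intervals),
                 mean_duration_ms = mean(edges$duration_ms),
                 sd_duration_ms = stats::sd(edges$duration_ms),
                 mean_interval_ms = mean(intervals),
                 sd_interval_ms = stats::sd(intervals),
                 n_pulses = nrow(edges)),
            class = "pulse_stats")
}

#' @export
print.pulse_stats <- function(x, ...) {
  cat(sprintf("<pulse_stats> %d pulses: duration %.3f +/- %.3f ms, interval %.3f +/- %.3f ms, freq %.3f Hz\n",
              x$n_pulses, x$mean_duration_ms, x$sd_duration_ms,
              x$mean_interval_ms, x$sd_interval_ms, x$freq_hz_est))
  invisible(x)
}

#' @describeIn pulse_stats Per-pulse table: `pulse`, `onset_ms`,
#'   `offset_ms`, `duration_ms`, `interval_ms` (NA for the first pulse).
#' @param x A `pulse_stats` object.
#' @param ... Unused.
#' @method tidy pulse_stats
#' @export
tidy.pulse_stats <- function(x, ...) {
  tibble(pulse = seq_along(x$onsets_ms), onset_ms = x$onsets_ms,
         offset_ms = x$offsets_ms, duration_ms = x$durations_ms,
         interval_ms = c(NA_real_, x$onset_intervals_ms))
}

#' @describeIn pulse_stats One-row summary with means, SDs and the
#'   frequency estimate.
#' @method glance pulse_stats
#' @export
glance.pulse_stats <- function(x, ...) {
  tibble(n_pulses = x$n_pulses, mean_duration_ms = x$mean_duration_ms,
         sd_duration_ms = x$sd_duration_ms,
         mean_interval_ms = x$mean_interval_ms,
         sd_interval_ms = x$sd_interval_ms, freq_hz_est = x$freq_hz_est)
}

#' Trigger-to-output lag per episode
#'
#' For each pulse onset on the trigger channel, the lag to the first
#' output onset at or after it. A trigger with no following output onset
#' (before the recording ends) is flagged with `NA`.
#'
#' @param trace A trace tibble.
#' @param trigger,output Trigger and output channel columns.
#' @param threshold_fraction Edge-detection threshold.
#' @return A tibble with `trigger_ms`, `output_ms`, `lag_ms`.
#' @export
trigger_lag <- function(trace, trigger, output, threshold_fraction = 0.5) {
  trig_on <- detect_edges(trace, {{ trigger }}, threshold_fraction)$onset_ms
  out_on <- detect_edges(trace, {{ output }}, threshold_fraction)$onset_ms
  if (is.unsorted(trig_on, strictly = TRUE)) {
    abort("trigger onsets must be strictly increasing.",
          class = "optopulse_analysis_error")
  }
  match_first <- function(tt) {
    nxt <- out_on[out_on >= tt]
    if (length(nxt)) nxt[1] else NA_real_
  }
  out_ms <- vapply(trig_on, match_first, 1)
  tibble(trigger_ms = trig_on, output_ms = out_ms,
         lag_ms = out_ms - trig_on)
}

#' Per-pulse onset offsets between two synchronised channels
#'
#' Pairs each pulse onset of channel A with the nearest onset of channel
#' B (after shifting by `expected_offset_ms`, so a deliberately delayed
#' train can be paired ordinally) and reports the per-pulse onset
#' differences B minus A. With unequal pulse counts only matched pairs
#' are reported; `n_unmatched_b` in the attributes records the rest.
#'
#' @param trace A trace tibble.
#' @param channel_a,channel_b Channel columns.
#' @param expected_offset_ms Known deliberate offset of B relative to A
#'   used as the pairing centre (default 0: plain nearest neighbour).
#' @param threshold_fraction Edge-detection threshold.
#' @return A tibble with `onset_a_ms`, `onset_b_ms`, `offset_ms`
#'   (= `onset_b_ms - onset_a_ms`).
#' @export
intersignal_offset <- function(trace, channel_a, channel_b,
                               expected_offset_ms = 0,
                               threshold_fraction = 0.5) {
  a <- detect_edges(trace, {{ channel_a }}, threshold_fraction)$onset_ms
  b <- detect_edges(trace, {{ channel_b }}, threshold_fraction)$onset_ms
  if (!length(a) || !length(b)) {
    abort("both channels must contain pulses.",
          class = "optopulse_analysis_error")
  }
  idx <- vapply(a + expected_offset_ms,
                function(target) which.min(abs(b - target)), 1L)
  out <- tibble(onset_a_ms = a, onset_b_ms = b[idx],
                offset_ms = b[idx] - a)
  attr(out, "n_unmatched_b") <- length(b) - length(unique(idx))
  out
}

#' Instantaneous phase by quadrature demodulation
#'
#' Estimates the per-sample phase of a channel oscillating at a known
#' frequency `f0_hz` by multiplying with cosine and sine carriers at `f0`
#' and low-pass filtering (moving average over one period), then taking
#' the four-quadrant arctangent. The convention follows the raised-cosine
#' waveform: an undelayed raised cosine at `f0` has phase 0; a pure time
#' delay `d` shifts the phase by `-2 pi f0 d`. Phases are wrapped to
#' (-pi, pi\]. Samples within half a period of either end are `NA` (the
#' moving-average window is incomplete there).
#'
#' @param trace A trace tibble.
#' @param channel Channel column.
#' @param f0_hz Known oscillation frequency in Hz (> 0).
#' @return A tibble with `t_s` and `phase_rad`.
#' @export
instantaneous_phase <- function(trace, channel, f0_hz) {
  x <- as.numeric(pull_channel(trace, {{ channel }}))
  check_scalar(f0_hz, "f0_hz", positive = TRUE)
  rate <- trace_rate_hz(trace)
  w <- max(2L, as.integer(round(rate / f0_hz)))
  if (length(x) < 2 * w) {
    abort("record shorter than 2 periods of f0.",
          class = "optopulse_analysis_error")
  }
  th <- 2 * pi * f0_hz * trace$t_s
  i_lp <- stats::filter(x * cos(th), rep(1 / w, w), sides = 2)
  q_lp <- stats::filter(x * sin(th), rep(1 / w, w), sides = 2)
  # x = C - B cos(2 pi f t + phi)  =>  I_lp = -(B/2) cos phi, Q_lp = (B/2) sin phi
  phase <- atan2(as.numeric(q_lp), -as.numeric(i_lp))
  tibble(t_s = trace$t_s, phase_rad = wrap_signed(phase))
}

wrap_signed <- function(x) {
  y <- ((x + pi) %% (2 * pi)) - pi
  y[!is.na(y) & y == -pi] <- pi          # range is (-pi, pi]
  y
}

wrap_positive <- function(x) x %% (2 * pi)

#' Circular statistics of the phase difference between two channels
#'
#' Computes per-sample instantaneous phases of both channels at `f0_hz`,
#' trims one period of transient at each end, and summarises the phase
#' difference (channel A minus channel B, so a delayed B gives a positive
#' offset) by its circular mean `atan2(sum sin, sum cos)` and resultant
#' length R.
#'
#' Two wrap conventions are offered for the reported angles: `"signed"`
#' maps to (-pi, pi\]; `"positive"` maps the same angles to \[0, 2 pi),
#' the natural scale when the difference is a delay-induced lag (and
#' numerically stable when the true offset sits at the +/- pi boundary,
#' where the signed convention's sign is decided by floating-point noise).
#'
#' @param trace A trace tibble.
#' @param channel_a,channel_b Channel columns (B is the delayed one in the
#'   delay-validation reading).
#' @param f0_hz Common oscillation frequency in Hz.
#' @param wrap `"signed"` or `"positive"`, see above.
#' @return An object of class `phase_stats` with fields
#'   `phase_diffs_rad`, `circ_mean_rad`, `resultant_length`, `n`,
#'   `f0_hz`, `wrap`.
#' @export
phase_difference_stats <- function(trace, channel_a, channel_b, f0_hz,
                                   wrap = c("signed", "positive")) {
  wrap <- match.arg(wrap)
  pa <- instantaneous_phase(trace, {{ channel_a }}, f0_hz)$phase_rad
  pb <- instantaneous_phase(trace, {{ channel_b }}, f0_hz)$phase_rad
  rate <- trace_rate_hz(trace)
  w <- max(2L, as.integer(round(rate / f0_hz)))
  keep <- seq_along(pa) > w & seq_along(pa) <= length(pa) - w
  d <- (pa - pb)[keep]
  d <- d[!is.na(d)]
  if (!length(d)) {
    abort("no usable samples after transient trimming.",
          class = "optopulse_analysis_error")
  }
  s <- sum(sin(d)); c <- sum(cos(d))
  m <- atan2(s, c)
  m <- if (wrap == "signed") wrap_signed(m) else wrap_positive(m)
  d <- if (wrap == "signed") wrap_signed(d) else wrap_positive(d)
  structure(list(phase_diffs_rad = d, circ_mean_rad = m,
                 resultant_length = sqrt(s^2 + c^2) / length(d),
                 n = length(d), f0_hz = f0_hz, wrap = wrap),
            class = "phase_stats")
}

#' @export
print.phase_stats <- function(x, ...) {
  cat(sprintf("<phase_stats> circular mean %.4f rad (R = %.4f, n = %d, f0 = %g Hz)\n",
              x$circ_mean_rad, x$resultant_length, x$n, x$f0_hz))
  invisible(x)
}

#' @describeIn phase_difference_stats Per-sample phase differences as a
#'   tibble.
#' @param x A `phase_stats` object.
#' @param ... Unused.
#' @method tidy phase_stats
#' @export
tidy.phase_stats <- function(x, ...) {
  tibble(sample = seq_along(x$phase_diffs_rad),
         phase_diff_rad = x$phase_diffs_rad)
}

#' @describeIn phase_difference_stats One-row summary: circular mean,
#'   resultant length, n.
#' @method glance phase_stats
#' @export
glance.phase_stats <- function(x, ...) {
  tibble(circ_mean_rad = x$circ_mean_rad,
         resultant_length = x$resultant_length, n = x$n, f0_hz = x$f0_hz)
}

#' Seeded random trigger train
#'
#' Generates `n` trigger times uniformly at random over `[0, t_max_s]`
#' with a minimum enforced gap between consecutive triggers, emulating an
#' external board delivering triggers at random moments. Fully
#' reproducible from `seed`; the caller's RNG state is left untouched.
#'
#' @param n Number of triggers (>= 1).
#' @param min_gap_ms Minimum gap between consecutive triggers in ms.
#' @param t_max_s Latest allowed trigger time in seconds.
#' @param seed Integer seed.
#' @param line Trigger line recorded in the event list.
#' @return An events tibble (`t_ms`, `kind = "trigger"`, `line`) ready for
#'   [run_device()].
#' @export
fixture_trigger_train <- function(n, min_gap_ms, t_max_s, seed = 1L,
                                  line = NA_integer_) {
  if (n < 1) abort("`n` must be >= 1.", class = "optopulse_param_error")
  t_max_ms <- t_max_s * 1000
  if (n * min_gap_ms > t_max_ms) {
    abort(sprintf("infeasible: %d triggers with %g ms gaps exceed %g ms.",
                  n, min_gap_ms, t_max_ms),
          class = "optopulse_param_error")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  slack <- t_max_ms - (n - 1) * min_gap_ms
  t <- sort(runif(n, 0, slack)) + (seq_len(n) - 1) * min_gap_ms
  tibble(t_ms = t, kind = "trigger", line = as.integer(line))
}
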