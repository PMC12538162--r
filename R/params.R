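#' Stimulation parameters for one laser channel
#'
#' Bundles the full stimulation description for a single laser channel:
#' waveform shape, train timing, optional attenuation ramp, trigger delay,
#' output power and whether the channel's masking LED mirrors it.
#'
#' Three waveforms are supported:
#' \describe{
#'   \item{`"square"`}{TTL-modulated pulse train. The pulse width is given
#'     either directly (`pulse_ms`) or as a duty cycle (`duty`, fraction of
#'     the period HIGH). If both are supplied they must agree. The analog
#'     control line is held constant over the train; the enable (TTL) line
#'     carries the pulses.}
#'   \item{`"sine"`}{Raised-cosine amplitude modulation
#'     \eqn{(1 - \cos 2\pi f t)/2}, so the envelope starts at zero and is
#'     non-negative (the analog line drives non-negative optical power).
#'     A pure-sine convention is available via the `sine_convention`
#'     argument of [render_channel()].}
#'   \item{`"half_sine"`}{Only the upper half of a sinusoid,
#'     \eqn{\max(0, \sin 2\pi f t)}: the signal rests at zero for half of
#'     every cycle.}
#' }
#'
#' For sinusoidal waveforms an attenuation ramp of `atten_ms` may be
#' appended: the train continues past `burst_ms` while the amplitude ramps
#' linearly to zero. The total active duration of a channel is therefore
#' `delay_ms + burst_ms + atten_ms` (attenuation extends the train; it is
#' not counted inside `burst_ms`). Attenuation does not apply to square
#' trains.
#'
#' @param laser_id Integer channel index, 1--4.
#' @param waveform One of `"square"`, `"sine"`, `"half_sine"`.
#' @param burst_ms Total duration of the pulse train in ms (> 0), excluding
#'   any attenuation tail.
#' @param freq_hz Pulse-train frequency in Hz (> 0).
#' @param pulse_ms Single-pulse duration in ms (square only). At least one
#'   of `pulse_ms`/`duty` must be given for square waveforms.
#' @param duty Fraction of each period HIGH, in (0, 1] (square only).
#' @param atten_ms Ramp-down duration in ms, >= 0 (sinusoidal waveforms
#'   only). The amplitude descends linearly to 0 over this window.
#' @param delay_ms Delay in ms between the accepted trigger and the start
#'   of the train, >= 0. Used to offset one train relative to another.
#' @param power Output power: percent of maximum in \[0, 100\] when
#'   `power_unit = "percent"`, or calibrated milliwatts when
#'   `power_unit = "mW"` (requires a [calib_fit()] curve at render time).
#' @param power_unit `"percent"` (default) or `"mW"`.
#' @param mask_enabled Should the channel's masking LED mirror the laser?
#'
#' @return An object of class `stim_params`.
#' @examples
#' stim_params(1, "square", burst_ms = 10000, freq_hz = 40, pulse_ms = 6)
#' stim_params(2, "sine", burst_ms = 800, freq_hz = 50, atten_ms = 200)
#' @export
stim_params <- function(laser_id, waveform = c("square", "sine", "half_sine"),
                        burst_ms, freq_hz, pulse_ms = NULL, duty = NULL,
                        atten_ms = 0, delay_ms = 0,
                        power = 100, power_unit = c("percent", "mW"),
                        mask_enabled = TRUE) {
  waveform <- match.arg(waveform)
  power_unit <- match.arg(power_unit)

  if (!is.numeric(laser_id) || length(laser_id) != 1L ||
      laser_id %% 1 != 0 || laser_id < 1 || laser_id > 4) {
    abort("`laser_id` must be a single integer in 1..4.",
          class = "optopulse_param_error")
  }
  check_scalar(burst_ms, "burst_ms", positive = TRUE)
  check_scalar(freq_hz, "freq_hz", positive = TRUE)
  check_scalar(atten_ms, "atten_ms", nonnegative = TRUE)
  check_scalar(delay_ms, "delay_ms", nonnegative = TRUE)
  check_scalar(power, "power", nonnegative = TRUE)
  if (power_unit == "percent" && power > 100) {
    abort("percent `power` must lie in [0, 100].",
          class = "optopulse_param_error")
  }

  period <- period_ms(freq_hz)

  if (waveform == "square") {
    if (is.null(pulse_ms) && is.null(duty)) {
      abort("square waveform needs `pulse_ms` or `duty`.",
            class = "optopulse_param_error")
    }
    if (!is.null(duty)) {
      check_scalar(duty, "duty", positive = TRUE)
      if (duty > 1) {
        abort("`duty` must lie in (0, 1].", class = "optopulse_param_error")
      }
    }
    if (!is.null(pulse_ms)) check_scalar(pulse_ms, "pulse_ms", positive = TRUE)
    if (!is.null(pulse_ms) && !is.null(duty) &&
        abs(pulse_ms * freq_hz / 1000 - duty) >= 1e-9) {
      abort(sprintf(
        "`pulse_ms` (%g ms) and `duty` (%g) disagree: pulse_ms * freq_hz / 1000 = %g.",
        pulse_ms, duty, pulse_ms * freq_hz / 1000),
        class = "optopulse_param_error")
    }
    width <- if (!is.null(pulse_ms)) pulse_ms else duty * period
    if (width > period + 1e-12) {
      abort(sprintf("pulse width %g ms exceeds the %g ms period.", width, period),
            class = "optopulse_param_error")
    }
    if (atten_ms > 0) {
      warn("attenuation applies to sinusoidal waveforms only; ignored for square.")
      atten_ms <- 0
    }
    pulse_ms <- width                      # canonical form
    duty <- width / period
  } else {
    if (!is.null(pulse_ms) || !is.null(duty)) {
      abort("`pulse_ms`/`duty` apply to square waveforms only.",
            class = "optopulse_param_error")
    }
  }

  structure(
    list(laser_id = as.integer(laser_id), waveform = waveform,
         burst_ms = as.numeric(burst_ms), freq_hz = as.numeric(freq_hz),
         pulse_ms = if (is.null(pulse_ms)) NULL else as.numeric(pulse_ms),
         duty = if (is.null(duty)) NULL else as.numeric(duty),
         atten_ms = as.numeric(atten_ms), delay_ms = as.numeric(delay_ms),
         power = as.numeric(power), power_unit = power_unit,
         mask_enabled = isTRUE(mask_enabled)),
    class = "stim_params")
}

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "optopulse_param_error")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name), class = "optopulse_param_error")
  }
  if (nonnegative && x < 0) {
    abort(sprintf("`%s` must be >= 0.", name), class = "optopulse_param_error")
  }
  invisible(x)
}

#' @export
print.stim_params <- function(x, ...) {
  cat(sprintf("<stim_params> laser %d: %s, %g Hz, burst %g ms",
              x$laser_id, x$waveform, x$freq_hz, x$burst_ms))
  if (x$waveform == "square") cat(sprintf(", pulse %g ms", x$pulse_ms))
  if (x$atten_ms > 0) cat(sprintf(", atten %g ms", x$atten_ms))
  if (x$delay_ms > 0) cat(sprintf(", delay %g ms", x$delay_ms))
  cat(sprintf(", power %g %s%s\n", x$power,
              if (x$power_unit == "percent") "%" else "mW",
              if (x$mask_enabled) ", mask on" else ""))
  invisible(x)
}

#' Pulse-train period in milliseconds
#'
#' @param freq_hz Frequency in Hz (> 0). Vectorised.
#' @return `1000 / freq_hz`, in ms (e.g. 40 Hz -> 25 ms).
#' @export
period_ms <- function(freq_hz) {
  if (!is.numeric(freq_hz) || any(!is.finite(freq_hz)) || any(freq_hz <= 0)) {
    abort("`freq_hz` must be positive and finite.",
          class = "optopulse_param_error")
  }
  1000 / freq_hz
}

#' Resolved single-pulse width of a square train
#'
#' Returns the pulse width in ms: `pulse_ms` when given, else
#' `duty * period`. Construction via [stim_params()] guarantees the result
#' lies in (0, period\].
#'
#' @param params A `stim_params` object with `waveform = "square"`.
#' @return Pulse width in ms.
#' @export
resolve_pulse_width <- function(params) {
  stopifnot(inherits(params, "stim_params"))
  if (params$waveform != "square") {
    abort("pulse width is defined for square waveforms only.",
          class = "optopulse_param_error")
  }
  if (!is.null(params$pulse_ms)) params$pulse_ms
  else params$duty * period_ms(params$freq_hz)
}

#' Total active duration of a channel after the trigger
#'
#' `delay_ms + burst_ms + atten_ms` for sinusoidal waveforms (the
#' attenuation ramp extends the train); `delay_ms + burst_ms` for square.
#'
#' @param params A `stim_params` object.
#' @return Duration in ms measured from trigger acceptance.
#' @export
active_duration_ms <- function(params) {
  stopifnot(inherits(params, "stim_params"))
  params$delay_ms + params$burst_ms +
    if (params$waveform == "square") 0 else params$atten_ms
}

#' Read / write stimulation parameter JSON files
#'
#' One JSON object per laser, keyed by `laser_id`, with the
#' [stim_params()] field names.
#'
#' @param path File path.
#' @param params_list A list of `stim_params` objects.
#' @return `read_params_json()` returns a named list of `stim_params`;
#'   `write_params_json()` returns `path` invisibly.
#' @export
write_params_json <- function(params_list, path) {
  if (inherits(params_list, "stim_params")) params_list <- list(params_list)
  obj <- lapply(params_list, params_to_list)
  names(obj) <- vapply(params_list, function(p) as.character(p$laser_id), "")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj, params_from_list)
}

params_to_list <- function(p) {
  out <- list(laser_id = p$laser_id, waveform = p$waveform,
              burst_ms = p$burst_ms, freq_hz = p$freq_hz)
  if (!is.null(p$pulse_ms)) out$pulse_ms <- p$pulse_ms
  out <- c(out, list(atten_ms = p$atten_ms, delay_ms = p$delay_ms,
                     power = p$power, power_unit = p$power_unit,
                     mask_enabled = p$mask_enabled))
  out
}

params_from_list <- function(x) {
  known <- c("laser_id", "waveform", "burst_ms", "freq_hz", "pulse_ms",
             "duty", "atten_ms", "delay_ms", "power", "power_unit",
             "mask_enabled")
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    abort(sprintf("unknown stimulation parameter field(s): %s",
                  paste(extra, collapse = ", ")),
          class = "optopulse_param_error")
  }
  required <- c("laser_id", "waveform", "burst_ms", "freq_hz")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("missing required stimulation parameter field(s): %s",
                  paste(missing, collapse = ", ")),
          class = "optopulse_param_error")
  }
  do.call(stim_params, x)
}
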