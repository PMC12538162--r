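#' Enable (TTL) line state at a time point
#'
#' Evaluates whether the laser-enable line is HIGH at time `t_ms`, measured
#' from trigger acceptance. For square trains the TTL carries the pulses:
#' HIGH iff `delay <= t < delay + burst` and the position within the period
#' is below the pulse width. For sinusoidal waveforms the enable line is
#' held HIGH continuously over the whole active window (including the
#' attenuation tail); the analog line carries the modulation.
#'
#' @param params A [stim_params()] object.
#' @param t_ms Time(s) in ms since trigger acceptance. Vectorised.
#' @return Logical vector.
#' @export
ttl_at <- function(params, t_ms) {
  stopifnot(inherits(params, "stim_params"))
  d <- params$delay_ms
  if (params$waveform == "square") {
    width <- resolve_pulse_width(params)
    per <- period_ms(params$freq_hz)
    in_burst <- t_ms >= d & t_ms < d + params$burst_ms
    in_burst & ((t_ms - d) %% per) < width
  } else {
    t_ms >= d & t_ms < d + params$burst_ms + params$atten_ms
  }
}

#' Linear attenuation ramp gain
#'
#' Amplitude gain applied to sinusoidal waveforms: 1 up to the end of the
#' burst, then a linear descent to 0 over the attenuation window
#' `(delay + burst, delay + burst + atten]`, and 0 afterwards. The pulse
#' train keeps oscillating during the ramp; only its amplitude shrinks.
#'
#' @inheritParams ttl_at
#' @return Numeric vector in \[0, 1\].
#' @export
attenuation_gain <- function(params, t_ms) {
  stopifnot(inherits(params, "stim_params"))
  if (params$waveform == "square") {
    abort("attenuation applies to sinusoidal waveforms only.",
          class = "optopulse_param_error")
  }
  ramp_start <- params$delay_ms + params$burst_ms
  a <- params$atten_ms
  g <- numeric(length(t_ms))
  g[t_ms <= ramp_start] <- 1
  if (a > 0) {
    in_ramp <- t_ms > ramp_start & t_ms <= ramp_start + a
    g[in_ramp] <- 1 - (t_ms[in_ramp] - ramp_start) / a
  }
  g
}

#' Analog control-line fraction at a time point
#'
#' Fraction of full analog scale (before power scaling and DAC
#' quantisation) at time `t_ms` since trigger acceptance:
#' \describe{
#'   \item{square}{constant 1 over the burst window -- the analog line is
#'     held stable while the TTL line is modulated; amplitude is carried by
#'     the power setting.}
#'   \item{sine}{raised cosine \eqn{(1 - \cos(2\pi f (t - delay)))/2}
#'     times the attenuation gain: starts at 0, peaks at 1 mid-period.
#'     With `sine_convention = "pure"`, a sinusoid about the half-scale
#'     midpoint, \eqn{(1 + \sin(2\pi f (t - delay)))/2}, is used instead.}
#'   \item{half_sine}{\eqn{\max(0, \sin(2\pi f (t - delay)))} times the
#'     attenuation gain: the signal rests at 0 for half of every cycle.}
#' }
#' Outside the active window the fraction is 0.
#'
#' @inheritParams ttl_at
#' @param sine_convention `"raised_cosine"` (default; envelope starts at 0)
#'   or `"pure"` (oscillation about the half-scale midpoint) -- `"sine"`
#'   waveform only.
#' @return Numeric vector in \[0, 1\].
#' @export
analog_fraction_at <- function(params, t_ms,
                               sine_convention = c("raised_cosine", "pure")) {
  stopifnot(inherits(params, "stim_params"))
  sine_convention <- match.arg(sine_convention)
  d <- params$delay_ms
  out <- numeric(length(t_ms))
  if (params$waveform == "square") {
    active <- t_ms >= d & t_ms < d + params$burst_ms
    out[active] <- 1
    return(out)
  }
  active <- t_ms >= d & t_ms < d + params$burst_ms + params$atten_ms
  if (!any(active)) return(out)
  ph <- 2 * pi * params$freq_hz * (t_ms[active] - d) / 1000
  base <- if (params$waveform == "sine") {
    if (sine_convention == "raised_cosine") (1 - cos(ph)) / 2
    else (1 + sin(ph)) / 2
  } else {
    pmax(0, sin(ph))
  }
  out[active] <- base * attenuation_gain(params, t_ms[active])
  out
}

#' Masking-LED line state at a time point
#'
#' The mask is a digital line driving an LED in the same pattern as the
#' laser, at the level a switched LED can realise: for square trains it
#' mirrors the laser TTL exactly; for sinusoidal waveforms it toggles at
#' the train frequency with 50% duty over the active window (a digital
#' driver cannot reproduce an analog envelope). Always LOW when
#' `mask_enabled` is `FALSE`.
#'
#' @inheritParams ttl_at
#' @return Logical vector.
#' @export
mask_at <- function(params, t_ms) {
  stopifnot(inherits(params, "stim_params"))
  if (!params$mask_enabled) return(rep(FALSE, length(t_ms)))
  if (params$waveform == "square") return(ttl_at(params, t_ms))
  d <- params$delay_ms
  per <- period_ms(params$freq_hz)
  active <- t_ms >= d & t_ms < d + params$burst_ms + params$atten_ms
  active & ((t_ms - d) %% per) < per / 2
}

#' Quantise a fraction onto a DAC code and output voltage
#'
#' Models an n-bit DAC spanning `[0, vref]` volts: the code is the
#' round-half-up nearest integer of `fraction * (2^bits - 1)` and the
#' output voltage is `code / (2^bits - 1) * vref`, so full scale maps to
#' the top code (4095 at 12 bits) and the quantisation error never exceeds
#' half an LSB.
#'
#' @param fraction Value(s) in \[0, 1\]. Vectorised.
#' @param bits DAC resolution in bits (default 12, i.e. 4096 codes).
#' @param vref Reference voltage in volts (default 5.0).
#' @return A tibble with columns `code` (integer) and `volts`.
#' @examples
#' quantize_dac(c(0, 0.5, 1))
#' @export
quantize_dac <- function(fraction, bits = 12L, vref = 5.0) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1)) {
    abort("`fraction` must lie in [0, 1].", class = "optopulse_param_error")
  }
  if (bits < 1) abort("`bits` must be >= 1.", class = "optopulse_param_error")
  full <- 2^bits - 1
  code <- floor(fraction * full + 0.5)     # round half up
  tibble(code = as.integer(code), volts = code / full * vref)
}

#' Render one channel's stimulation as a uniformly sampled trace
#'
#' Evaluates the TTL, analog and mask lines of a single channel on a
#' uniform sample grid starting at the moment of trigger acceptance
#' (t = 0). The analog fraction is scaled by the power setting (percent of
#' maximum, or milliwatts through a calibration curve) and quantised
#' through the DAC model, so `analog_V` contains exact DAC-representable
#' voltages.
#'
#' @param params A [stim_params()] object.
#' @param rate_hz Sampling rate in Hz (> 0). A rate above twice the train
#'   frequency is recommended; a warning is issued otherwise.
#' @param total_s Total rendered duration in seconds.
#' @param calibration A [calib_fit()] curve, required when
#'   `params$power_unit == "mW"`.
#' @param bits,vref DAC depth and reference voltage.
#' @param sine_convention Passed to [analog_fraction_at()].
#' @return A tibble of class `laser_trace` with columns `t_s` (seconds),
#'   `analog_V`, `ttl`, `mask`; the sampling rate is stored in the
#'   `rate_hz` attribute.
#' @examples
#' p <- stim_params(1, "square", burst_ms = 250, freq_hz = 40, pulse_ms = 6)
#' tr <- render_channel(p, rate_hz = 2000, total_s = 0.3)
#' @export
render_channel <- function(params, rate_hz, total_s, calibration = NULL,
                           bits = 12L, vref = 5.0,
                           sine_convention = c("raised_cosine", "pure")) {
  stopifnot(inherits(params, "stim_params"))
  check_scalar(rate_hz, "rate_hz", positive = TRUE)
  check_scalar(total_s, "total_s", positive = TRUE)
  if (rate_hz <= 2 * params$freq_hz) {
    warn(sprintf("sampling rate %g Hz is not above twice the train frequency (%g Hz); timing estimates will be unreliable.",
                 rate_hz, params$freq_hz))
  }
  n <- floor(total_s * rate_hz + 1e-9)
  t_s <- (seq_len(n) - 1) / rate_hz
  t_ms <- t_s * 1000
  pf <- power_fraction(params, calibration)
  frac <- analog_fraction_at(params, t_ms, sine_convention) * pf
  q <- quantize_dac(frac, bits = bits, vref = vref)
  new_laser_trace(
    tibble(t_s = t_s, analog_V = q$volts, ttl = ttl_at(params, t_ms),
           mask = mask_at(params, t_ms)),
    rate_hz = rate_hz)
}

power_fraction <- function(params, calibration = NULL) {
  if (params$power_unit == "percent") return(params$power / 100)
  if (is.null(calibration)) {
    abort("`power_unit = \"mW\"` requires a calibration curve.",
          class = "optopulse_param_error")
  }
  mw_to_fraction(calibration, params$power)
}

new_laser_trace <- function(df, rate_hz) {
  out <- as_tibble(df)
  attr(out, "rate_hz") <- rate_hz
  class(out) <- c("laser_trace", class(out))
  out
}

#' Sampling rate of a trace
#'
#' Returns the `rate_hz` attribute when present, otherwise infers it from
#' the spacing of `t_s` (which must be constant).
#'
#' @param trace A trace tibble with a `t_s` column in seconds.
#' @return Sampling rate in Hz.
#' @export
trace_rate_hz <- function(trace) {
  r <- attr(trace, "rate_hz")
  if (!is.null(r)) return(r)
  dt <- diff(trace$t_s)
  if (length(dt) == 0) abort("trace has fewer than 2 samples.")
  if (diff(range(dt)) > 1e-9 * mean(dt)) {
    abort("trace sample spacing is not constant.")
  }
  1 / mean(dt)
}
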