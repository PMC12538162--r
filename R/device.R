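#' Virtual controller configuration
#'
#' Static configuration of the emulated stimulation controller.
#'
#' @param n_lasers Number of laser channels (the hardware caps at 4).
#' @param debounce_ms Trigger debounce window in ms: a trigger edge
#'   arriving less than this after the previous edge on the selected line
#'   is ignored. Default 5 ms.
#' @param trigger_line Selected trigger input, 1--6.
#' @param priming_required When `TRUE`, only trigger edges coinciding with
#'   a primed (armed) state start stimulation; a prime arms exactly one
#'   acceptance.
#' @param standalone Standalone operation (parameters and software triggers
#'   from the host GUI); disables the CommEnable line.
#' @param ttl_high_V Nominal HIGH level of the digital outputs (3.3 V).
#' @param dac_bits,dac_vref_V DAC depth (12 bits -> 4096 codes) and analog
#'   full-scale voltage (5 V).
#' @param heartbeat_hz Idle status-LED blink rate (6 Hz).
#' @param loop_latency_ms Constant trigger-to-output lag added to each
#'   episode start, emulating the firmware main-loop latency of a physical
#'   board. Default 0 (ideal device).
#' @param trigger_polarity Which transition on the trigger line counts as
#'   an edge; `"rising"` (drive the pin HIGH to start) is the default.
#' @param sine_convention Sinusoid convention used when rendering, see
#'   [analog_fraction_at()].
#' @return A `device_config` list.
#' @export
device_config <- function(n_lasers = 4L, debounce_ms = 5, trigger_line = 1L,
                          priming_required = FALSE, standalone = FALSE,
                          ttl_high_V = 3.3, dac_bits = 12L, dac_vref_V = 5.0,
                          heartbeat_hz = 6, loop_latency_ms = 0,
                          trigger_polarity = c("rising", "falling"),
                          sine_convention = c("raised_cosine", "pure")) {
  trigger_polarity <- match.arg(trigger_polarity)
  sine_convention <- match.arg(sine_convention)
  if (debounce_ms < 0) abort("`debounce_ms` must be >= 0.")
  if (!trigger_line %in% 1:6) abort("`trigger_line` must be in 1..6.")
  if (dac_bits < 1) abort("`dac_bits` must be >= 1.")
  if (n_lasers < 1 || n_lasers > 4) abort("`n_lasers` must be in 1..4.")
  structure(list(n_lasers = as.integer(n_lasers), debounce_ms = debounce_ms,
                 trigger_line = as.integer(trigger_line),
                 priming_required = priming_required, standalone = standalone,
                 ttl_high_V = ttl_high_V, dac_bits = as.integer(dac_bits),
                 dac_vref_V = dac_vref_V, heartbeat_hz = heartbeat_hz,
                 loop_latency_ms = loop_latency_ms,
                 trigger_polarity = trigger_polarity,
                 sine_convention = sine_convention),
            class = "device_config")
}

#' Create a virtual stimulation controller
#'
#' Builds an emulated controller holding per-channel stimulation
#' parameters, the trigger/priming/debounce state machine and the episode
#' log. The device is an environment, so the mutators ([set_params()],
#' [on_trigger_edge()], [device_step()], ...) update it in place and return
#' the device (or the acceptance flag) invisibly -- reference semantics,
#' like a physical instrument handle.
#'
#' The device is in one of three states: `IDLE`, `PRIMED` (armed, only
#' when `priming_required`) or `STIMULATING` (an episode is running).
#'
#' @param config A [device_config()].
#' @return An object of class `virtual_device`.
#' @examples
#' dev <- virtual_device()
#' set_params(dev, stim_params(1, "square", burst_ms = 100,
#'                             freq_hz = 40, pulse_ms = 6))
#' on_trigger_edge(dev, t_ms = 10)
#' @export
virtual_device <- function(config = device_config()) {
  stopifnot(inherits(config, "device_config"))
  dev <- new.env(parent = emptyenv())
  dev$config <- config
  dev$params <- vector("list", config$n_lasers)
  dev$calibration <- vector("list", config$n_lasers)
  dev$mock <- FALSE
  dev$primed <- FALSE
  dev$t_last_edge <- -Inf
  dev$t_now <- 0
  dev$episode <- NULL          # list(accept_ms, start_ms, end_ms, params, mock)
  dev$episode_log <- list()
  class(dev) <- "virtual_device"
  dev
}

#' @export
print.virtual_device <- function(x, ...) {
  cat(sprintf("<virtual_device> %d lasers, state %s at t = %g ms, %d episode(s) logged\n",
              x$config$n_lasers, device_state(x), x$t_now,
              length(x$episode_log)))
  invisible(x)
}

#' Current device state
#'
#' @param device A [virtual_device()].
#' @param t_ms Time in ms (defaults to the device clock).
#' @return `"IDLE"`, `"PRIMED"` or `"STIMULATING"`.
#' @export
device_state <- function(device, t_ms = device$t_now) {
  if (device_busy(device, t_ms)) "STIMULATING"
  else if (device$primed && device$config$priming_required) "PRIMED"
  else "IDLE"
}

device_busy <- function(device, t_ms) {
  !is.null(device$episode) && t_ms < device$episode$end_ms
}

expire_episode <- function(device, t_ms) {
  if (!is.null(device$episode) && t_ms >= device$episode$end_ms) {
    device$episode <- NULL
  }
}

#' Load stimulation parameters onto the device
#'
#' Replaces the per-channel parameters. The device accepts new parameters
#' only while idle (CommEnable LOW); during an episode a device-busy error
#' is raised -- parameters are rejected, not queued.
#'
#' @param device A [virtual_device()].
#' @param params A [stim_params()] object or a list of them (one per laser;
#'   duplicate `laser_id`s are an error).
#' @param t_ms Time of the request in ms.
#' @return The device, invisibly.
#' @export
set_params <- function(device, params, t_ms = device$t_now) {
  stopifnot(inherits(device, "virtual_device"))
  expire_episode(device, t_ms)
  if (device_busy(device, t_ms)) {
    abort("device busy: parameters are not accepted during stimulation.",
          class = "optopulse_busy_error")
  }
  if (inherits(params, "stim_params")) params <- list(params)
  ok <- vapply(params, inherits, TRUE, what = "stim_params")
  if (!all(ok)) abort("`params` must be stim_params objects.",
                      class = "optopulse_param_error")
  ids <- vapply(params, function(p) p$laser_id, 1L)
  if (anyDuplicated(ids)) abort("duplicate laser_id in parameter set.",
                                class = "optopulse_param_error")
  if (any(ids > device$config$n_lasers)) {
    abort(sprintf("laser_id beyond the device's %d channels.",
                  device$config$n_lasers),
          class = "optopulse_param_error")
  }
  device$params <- vector("list", device$config$n_lasers)
  for (p in params) device$params[[p$laser_id]] <- p
  invisible(device)
}

#' Attach a power calibration to a laser channel
#'
#' Required before rendering parameters whose power is given in mW.
#'
#' @param device A [virtual_device()].
#' @param curve A [calib_fit()] curve (its `laser_id` selects the channel).
#' @return The device, invisibly.
#' @export
set_calibration <- function(device, curve) {
  stopifnot(inherits(device, "virtual_device"),
            inherits(curve, "calibration_curve"))
  device$calibration[[curve$laser_id]] <- curve
  invisible(device)
}

#' Toggle mock (mask-only) trials
#'
#' When the mock flag is set, the next stimulation episode drives the
#' masking LEDs only: every laser analog output stays at 0 V and every TTL
#' line LOW for the whole episode. Used to implement control trials in
#' which the animal sees the masking flash but receives no laser light.
#' The flag applies to whole episodes and can be changed between them.
#'
#' @param device A [virtual_device()].
#' @param flag Logical.
#' @param t_ms Time of the request in ms.
#' @return The device, invisibly. Errors when the device is mid-episode.
#' @export
set_mock <- function(device, flag, t_ms = device$t_now) {
  stopifnot(inherits(device, "virtual_device"))
  expire_episode(device, t_ms)
  if (device_busy(device, t_ms)) {
    abort("device busy: mock flag cannot change during stimulation.",
          class = "optopulse_busy_error")
  }
  device$mock <- isTRUE(flag)
  invisible(device)
}

#' Priming-line edge
#'
#' A rising edge on the priming pin arms the device: with
#' `priming_required`, only the next trigger edge will start stimulation
#' (repeated triggers after that single acceptance are ignored until the
#' device is primed again). A falling edge clears the armed state.
#'
#' @param device A [virtual_device()].
#' @param t_ms Edge time in ms.
#' @param edge `"rising"` (arm) or `"falling"` (disarm).
#' @return The device, invisibly.
#' @export
on_prime_edge <- function(device, t_ms, edge = c("rising", "falling")) {
  stopifnot(inherits(device, "virtual_device"))
  edge <- match.arg(edge)
  device$t_now <- max(device$t_now, t_ms)
  device$primed <- (edge == "rising")
  invisible(device)
}

#' Trigger-line edge
#'
#' Processes one edge on a trigger input. The edge is accepted -- and an
#' episode started -- iff all of: it arrives on the configured line; at
#' least `debounce_ms` has elapsed since the previous edge on that line;
#' the device is not already stimulating; and the device is primed (or
#' priming is not required). Acceptance consumes the prime. Every active
#' channel starts with its own `delay_ms` relative to the (possibly
#' latency-shifted) episode start.
#'
#' @param device A [virtual_device()].
#' @param t_ms Edge time in ms. Edges must be fed in time order.
#' @param line Trigger input the edge arrived on; edges on non-selected
#'   lines are ignored.
#' @return `TRUE` if the edge was accepted, else `FALSE` (invisibly the
#'   same value); the decision and its reason are appended to the episode
#'   log.
#' @export
on_trigger_edge <- function(device, t_ms,
                            line = device$config$trigger_line) {
  stopifnot(inherits(device, "virtual_device"))
  device$t_now <- max(device$t_now, t_ms)
  if (line != device$config$trigger_line) {
    log_event(device, t_ms, "trigger", FALSE, "non-selected line")
    return(invisible(FALSE))
  }
  since <- t_ms - device$t_last_edge
  device$t_last_edge <- t_ms
  expire_episode(device, t_ms)
  reason <- if (since < device$config$debounce_ms) "debounced"
    else if (device_busy(device, t_ms)) "busy"
    else if (device$config$priming_required && !device$primed) "not primed"
    else NA_character_
  accepted <- is.na(reason)
  if (accepted) {
    start_episode(device, t_ms)
    reason <- "accepted"
  }
  log_event(device, t_ms, "trigger", accepted, reason)
  invisible(accepted)
}

#' Software trigger
#'
#' Starts an episode on request from the host (GUI "send trigger" button):
#' bypasses trigger-line selection, debouncing and priming, but is still
#' rejected while an episode is running.
#'
#' @param device A [virtual_device()].
#' @param t_ms Request time in ms.
#' @return `TRUE` if accepted, `FALSE` if the device was busy.
#' @export
software_trigger <- function(device, t_ms = device$t_now) {
  stopifnot(inherits(device, "virtual_device"))
  device$t_now <- max(device$t_now, t_ms)
  expire_episode(device, t_ms)
  if (device_busy(device, t_ms)) {
    log_event(device, t_ms, "software_trigger", FALSE, "busy")
    return(invisible(FALSE))
  }
  start_episode(device, t_ms)
  log_event(device, t_ms, "software_trigger", TRUE, "accepted")
  invisible(TRUE)
}

start_episode <- function(device, t_ms) {
  active <- Filter(Negate(is.null), device$params)
  start <- t_ms + device$config$loop_latency_ms
  ends <- vapply(active, active_duration_ms, 1)
  device$episode <- list(
    accept_ms = t_ms, start_ms = start,
    end_ms = if (length(ends)) start + max(ends) else start,
    params = active, mock = device$mock)
  device$primed <- FALSE       # a prime arms exactly one acceptance
  invisible(device)
}

log_event <- function(device, t_ms, kind, accepted, reason) {
  device$episode_log[[length(device$episode_log) + 1L]] <-
    list(t_ms = t_ms, kind = kind, accepted = accepted, reason = reason)
}

#' Episode / event log as a tibble
#'
#' @param device A [virtual_device()].
#' @return A tibble with one row per processed trigger event: `t_ms`,
#'   `kind`, `accepted`, `reason`.
#' @export
episode_log <- function(device) {
  stopifnot(inherits(device, "virtual_device"))
  if (!length(device$episode_log)) {
    return(tibble(t_ms = numeric(), kind = character(),
                  accepted = logical(), reason = character()))
  }
  purrr::map_dfr(device$episode_log, as_tibble)
}

#' Sample the device outputs at a time point
#'
#' Advances the device clock to `t_ms` (time must not move backwards) and
#' returns the state of every output line. When the running episode has
#' passed its last channel's `delay + burst (+ atten)` window the device
#' returns to `IDLE` and all lines read low.
#'
#' @param device A [virtual_device()].
#' @param t_ms Sample time in ms; monotone nondecreasing across calls.
#' @return A tibble with one row per laser channel: `laser`, `analog_V`,
#'   `ttl`, `mask`, plus the device `state` as an attribute-free column.
#' @export
device_step <- function(device, t_ms) {
  stopifnot(inherits(device, "virtual_device"))
  if (t_ms < device$t_now) {
    abort(sprintf("time moving backwards: step at %g ms after clock %g ms.",
                  t_ms, device$t_now),
          class = "optopulse_time_error")
  }
  device$t_now <- t_ms
  expire_episode(device, t_ms)
  snap <- outputs_at(device, t_ms)
  snap$state <- device_state(device, t_ms)
  snap
}

outputs_at <- function(device, t_ms) {
  cfg <- device$config
  out <- tibble(laser = seq_len(cfg$n_lasers),
                analog_V = 0, ttl = FALSE, mask = FALSE)
  ep <- device$episode
  if (is.null(ep) || t_ms < ep$start_ms || t_ms >= ep$end_ms) return(out)
  t_rel <- t_ms - ep$start_ms
  for (p in ep$params) {
    i <- p$laser_id
    out$mask[i] <- mask_at(p, t_rel)
    if (!ep$mock) {
      frac <- analog_fraction_at(p, t_rel, cfg$sine_convention) *
        power_fraction(p, device$calibration[[i]])
      out$analog_V[i] <- quantize_dac(frac, cfg$dac_bits, cfg$dac_vref_V)$volts
      out$ttl[i] <- ttl_at(p, t_rel)
    }
  }
  out
}

#' CommEnable line
#'
#' The CommEnable pin tells the host whether the board is busy: HIGH while
#' an episode is running (no new parameters accepted, only trigger signals
#' awaited), LOW when idle. Always LOW in standalone mode, where the line
#' is disabled.
#'
#' @param device A [virtual_device()].
#' @param t_ms Time in ms.
#' @return Logical.
#' @export
comm_enable <- function(device, t_ms = device$t_now) {
  stopifnot(inherits(device, "virtual_device"))
  if (device$config$standalone) return(FALSE)
  device_busy(device, t_ms)
}

#' Status-LED heartbeat
#'
#' The board's LED blinks as a square wave at `heartbeat_hz` (period
#' `1000/6` ms at the 6 Hz default) while the device is idle, starting
#' HIGH at t = 0; the blink is suppressed during an episode.
#'
#' @param device A [virtual_device()].
#' @param t_ms Time(s) in ms. Vectorised.
#' @return Logical vector: LED state.
#' @export
heartbeat <- function(device, t_ms) {
  stopifnot(inherits(device, "virtual_device"))
  per <- 1000 / device$config$heartbeat_hz
  busy <- vapply(t_ms, function(t) device_busy(device, t), TRUE)
  !busy & (t_ms %% per) < per / 2
}

#' Drive the device through an event list and render the full trace
#'
#' Replays a timestamped event list (trigger and priming edges, mock
#' toggles) through the state machine, then renders the multichannel
#' output on a uniform sample grid. Episodes never overlap (the device is
#' busy until the last channel finishes), so the trace is assembled
#' episode by episode with vectorised waveform evaluation; the result is
#' bit-identical to stepping the device sample by sample.
#'
#' @param device A [virtual_device()] (consumed: its log and state are
#'   updated in place).
#' @param events A tibble/data frame with columns `t_ms`, `kind` (one of
#'   `"trigger"`, `"prime"`, `"prime_off"`, `"mock_on"`, `"mock_off"`,
#'   `"software_trigger"`) and optionally `line` (defaults to the
#'   configured trigger line). Processed in time order.
#' @param rate_hz Sampling rate in Hz.
#' @param t_end_s Total duration of the rendered trace in seconds.
#' @param trigger_pulse_ms Width of the rendered trigger-line pulse for
#'   each trigger event (the physical line, all edges), default 2 ms.
#' @return A list of class `device_run`: `$trace` (a `laser_trace` tibble
#'   with `t_s`, per-channel `laser<i>_V` / `laser<i>_ttl` / `mask<i>`, and
#'   `trigger`), `$events` (the episode log), `$config`.
#' @export
run_device <- function(device, events, rate_hz, t_end_s,
                       trigger_pulse_ms = 2) {
  stopifnot(inherits(device, "virtual_device"))
  check_scalar(rate_hz, "rate_hz", positive = TRUE)
  check_scalar(t_end_s, "t_end_s", positive = TRUE)
  events <- validate_events(events)
  n_before <- length(device$episode_log)
  accepted_eps <- list()

  for (i in seq_len(nrow(events))) {
    t <- events$t_ms[i]
    kind <- events$kind[i]
    line <- events$line[i]
    if (is.na(line)) line <- device$config$trigger_line
    switch(kind,
      trigger = {
        if (on_trigger_edge(device, t, line)) {
          accepted_eps[[length(accepted_eps) + 1L]] <- device$episode
        }
      },
      software_trigger = {
        if (software_trigger(device, t)) {
          accepted_eps[[length(accepted_eps) + 1L]] <- device$episode
        }
      },
      prime = on_prime_edge(device, t, "rising"),
      prime_off = on_prime_edge(device, t, "falling"),
      mock_on = try_set_mock(device, TRUE, t),
      mock_off = try_set_mock(device, FALSE, t),
      abort(sprintf("unknown event kind '%s'.", kind),
            class = "optopulse_event_error")
    )
  }

  n <- floor(t_end_s * rate_hz + 1e-9)
  t_s <- (seq_len(n) - 1) / rate_hz
  t_ms <- t_s * 1000
  cfg <- device$config
  cols <- list(t_s = t_s)
  for (ch in seq_len(cfg$n_lasers)) {
    cols[[paste0("laser", ch, "_V")]] <- numeric(n)
    cols[[paste0("laser", ch, "_ttl")]] <- logical(n)
    cols[[paste0("mask", ch)]] <- logical(n)
  }
  for (ep in accepted_eps) {
    idx <- which(t_ms >= ep$start_ms & t_ms < ep$end_ms)
    if (!length(idx)) next
    t_rel <- t_ms[idx] - ep$start_ms
    for (p in ep$params) {
      ch <- p$laser_id
      cols[[paste0("mask", ch)]][idx] <- mask_at(p, t_rel)
      if (!ep$mock) {
        frac <- analog_fraction_at(p, t_rel, cfg$sine_convention) *
          power_fraction(p, device$calibration[[ch]])
        cols[[paste0("laser", ch, "_V")]][idx] <-
          quantize_dac(frac, cfg$dac_bits, cfg$dac_vref_V)$volts
        cols[[paste0("laser", ch, "_ttl")]][idx] <- ttl_at(p, t_rel)
      }
    }
  }
  trig <- logical(n)
  trig_times <- events$t_ms[events$kind == "trigger"]
  for (tt in trig_times) {
    trig[t_ms >= tt & t_ms < tt + trigger_pulse_ms] <- TRUE
  }
  cols$trigger <- trig

  log <- episode_log(device)
  new_log <- if (nrow(log) > n_before) {
    log[(n_before + 1L):nrow(log), , drop = FALSE]
  } else log[0, , drop = FALSE]
  structure(list(trace = new_laser_trace(as_tibble(cols), rate_hz),
                 events = new_log,
                 config = cfg),
            class = "device_run")
}

try_set_mock <- function(device, flag, t_ms) {
  res <- tryCatch({set_mock(device, flag, t_ms); "accepted"},
                  optopulse_busy_error = function(e) "busy")
  log_event(device, t_ms, if (flag) "mock_on" else "mock_off",
            res == "accepted", res)
}

validate_events <- function(events) {
  events <- as_tibble(events)
  need <- c("t_ms", "kind")
  if (!all(need %in% names(events))) {
    abort("events need columns `t_ms` and `kind`.",
          class = "optopulse_event_error")
  }
  if (!"line" %in% names(events)) events$line <- NA_integer_
  if (any(!is.finite(events$t_ms))) {
    abort("event times must be finite.", class = "optopulse_event_error")
  }
  dplyr::arrange(events, .data$t_ms)
}

#' @export
print.device_run <- function(x, ...) {
  acc <- sum(x$events$accepted)
  cat(sprintf("<device_run> %d samples at %g Hz, %d/%d events accepted\n",
              nrow(x$trace), trace_rate_hz(x$trace), acc, nrow(x$events)))
  invisible(x)
}
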