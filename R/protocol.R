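#' Control-protocol message
#'
#' The host talks to the controller in line-delimited JSON: each message is
#' a single JSON object followed by exactly one line-break character. Five
#' message kinds exist: `PARAMS` (upload a list of per-laser stimulation
#' parameters), `TRIGGER` (software trigger), `MOCK` (set the mask-only
#' flag), `PING` (echo request) and `CALIBRATE` (run the stepped-intensity
#' calibration schedule). The wire schema uses the [stim_params()] field
#' names and a top-level `kind` key, so a firmware port could adopt it
#' directly.
#'
#' @param kind One of `"PARAMS"`, `"TRIGGER"`, `"MOCK"`, `"PING"`,
#'   `"CALIBRATE"`.
#' @param payload Kind-specific payload: a list of `stim_params` for
#'   `PARAMS`; `list(flag = <logical>)` for `MOCK`; optionally
#'   `list(steps = <fractions>)` for `CALIBRATE`; empty otherwise.
#' @return An object of class `laser_msg`.
#' @export
laser_msg <- function(kind = c("PARAMS", "TRIGGER", "MOCK", "PING", "CALIBRATE"),
                      payload = list()) {
  kind <- match.arg(kind)
  if (kind == "PARAMS") {
    ok <- is.list(payload) &&
      all(vapply(payload, inherits, TRUE, what = "stim_params"))
    if (!ok || !length(payload)) {
      abort("PARAMS payload must be a non-empty list of stim_params.",
            class = "optopulse_protocol_error")
    }
  }
  if (kind == "MOCK" && !is.logical(payload$flag)) {
    abort("MOCK payload must carry a logical `flag`.",
          class = "optopulse_protocol_error")
  }
  structure(list(kind = kind, payload = payload), class = "laser_msg")
}

#' Encode a message as one JSON line
#'
#' Serialises a message to UTF-8 JSON terminated by a single `"\n"`. Key
#' order is fixed by construction so encoding is reproducible; non-finite
#' numbers are rejected (JSON has no NaN/Inf).
#'
#' @param msg A [laser_msg()].
#' @return A single string ending in `"\n"`.
#' @export
encode_message <- function(msg) {
  stopifnot(inherits(msg, "laser_msg"))
  payload <- msg$payload
  if (msg$kind == "PARAMS") {
    payload <- lapply(payload, params_to_list)
  }
  check_finite_payload(payload)
  body <- c(list(kind = msg$kind), list(payload = payload))
  txt <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, null = "null")
  paste0(as.character(txt), "\n")
}

check_finite_payload <- function(x) {
  if (is.list(x)) {
    lapply(x, check_finite_payload)
  } else if (is.numeric(x) && any(!is.finite(x))) {
    abort("payload contains non-finite numbers (NaN/Inf are not serialisable).",
          class = "optopulse_protocol_error")
  }
  invisible(NULL)
}

#' Decode one protocol line into a message
#'
#' Parses a complete line back into a [laser_msg()]. Malformed JSON, an
#' unknown `kind`, or a payload violating the parameter schema raise
#' classed errors with field-level diagnostics.
#'
#' @param line A single line of text (trailing newline optional).
#' @return A `laser_msg`.
#' @export
decode_message <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  obj <- tryCatch(
    jsonlite::fromJSON(line, simplifyVector = FALSE),
    error = function(e) {
      abort(paste0("malformed JSON: ", conditionMessage(e)),
            class = c("optopulse_malformed_error", "optopulse_protocol_error"))
    })
  kinds <- c("PARAMS", "TRIGGER", "MOCK", "PING", "CALIBRATE")
  if (is.null(obj$kind) || !obj$kind %in% kinds) {
    abort(sprintf("unknown message kind '%s'.", obj$kind %||% "<missing>"),
          class = c("optopulse_unknown_kind_error", "optopulse_protocol_error"))
  }
  payload <- obj$payload %||% list()
  if (obj$kind == "PARAMS") {
    payload <- tryCatch(
      lapply(payload, params_from_list),
      optopulse_param_error = function(e) {
        abort(paste0("PARAMS schema violation: ", conditionMessage(e)),
              class = c("optopulse_schema_error", "optopulse_protocol_error"))
      })
  }
  if (obj$kind == "CALIBRATE" && !is.null(payload$steps)) {
    payload$steps <- as.numeric(unlist(payload$steps))
  }
  if (obj$kind == "MOCK") {
    if (!is.logical(payload$flag)) {
      abort("MOCK schema violation: payload must carry a logical `flag`.",
            class = c("optopulse_schema_error", "optopulse_protocol_error"))
    }
  }
  laser_msg(obj$kind, payload)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Route a decoded message to the virtual device
#'
#' Executes the message against the device and returns the reply. Every
#' request gets exactly one reply (also a single JSON-serialisable list):
#' `ok` plus kind-specific fields. A busy device surfaces as an
#' `ok = FALSE` reply with `error = "busy"`, never as an exception -- the
#' host must be able to keep talking to a busy board.
#'
#' @param device A [virtual_device()].
#' @param msg A [laser_msg()].
#' @param t_ms Time of message arrival in ms.
#' @return A reply list with elements `reply_to`, `ok` and extras.
#' @export
dispatch_message <- function(device, msg, t_ms = device$t_now) {
  stopifnot(inherits(device, "virtual_device"), inherits(msg, "laser_msg"))
  reply <- function(ok, ...) list(reply_to = msg$kind, ok = ok, ...)
  switch(msg$kind,
    PING = reply(TRUE, echo = TRUE),
    PARAMS = tryCatch({
      set_params(device, msg$payload, t_ms)
      reply(TRUE, n_channels = length(msg$payload))
    },
    optopulse_busy_error = function(e) reply(FALSE, error = "busy"),
    optopulse_param_error = function(e)
      reply(FALSE, error = conditionMessage(e))),
    TRIGGER = {
      acc <- software_trigger(device, t_ms)
      if (acc) reply(TRUE) else reply(FALSE, error = "busy")
    },
    MOCK = tryCatch({
      set_mock(device, msg$payload$flag, t_ms)
      reply(TRUE, mock = device$mock)
    },
    optopulse_busy_error = function(e) reply(FALSE, error = "busy")),
    CALIBRATE = {
      steps <- msg$payload$steps %||% calib_steps_default()
      steps <- as.numeric(unlist(steps))
      reply(TRUE, steps = steps, pulse_s = 10)
    })
}

#' Line buffer for a byte-stream transport
#'
#' The protocol runs over an abstract byte stream (loopback, file or
#' serial port). Chunks may split messages anywhere; `feed_chunk()`
#' accumulates text, emits every complete line (without its terminator)
#' and retains the trailing partial line for the next chunk, so no bytes
#' are ever dropped regardless of fragmentation.
#'
#' @return `line_buffer()` returns a buffer object; `feed_chunk()` returns
#'   a character vector of completed lines (possibly empty).
#' @export
line_buffer <- function() {
  buf <- new.env(parent = emptyenv())
  buf$pending <- ""
  class(buf) <- "line_buffer"
  buf
}

#' @param buffer A [line_buffer()].
#' @param chunk A character scalar: the next fragment of the stream.
#' @rdname line_buffer
#' @export
feed_chunk <- function(buffer, chunk) {
  stopifnot(inherits(buffer, "line_buffer"), is.character(chunk))
  text <- paste0(buffer$pending, paste(chunk, collapse = ""))
  parts <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (endsWith(text, "\n")) {
    buffer$pending <- ""
    complete <- parts
  } else {
    buffer$pending <- if (length(parts)) parts[length(parts)] else ""
    complete <- if (length(parts) > 1) parts[-length(parts)] else character()
  }
  complete[nzchar(complete)]
}
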