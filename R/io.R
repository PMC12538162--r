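#' Read / write trace CSV files
#'
#' Traces are exchanged as plain CSV with a `t_s` column (seconds) and one
#' column group per channel (`laser<i>_V`, `laser<i>_ttl`, `mask<i>`, plus
#' `trigger` for device runs). Logical TTL/mask/trigger lines are written
#' as 0/1 and restored to logical on read.
#'
#' @param trace A trace tibble.
#' @param path File path.
#' @return `read_trace()` returns a `laser_trace` tibble;
#'   `write_trace()` returns `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  out <- as_tibble(trace)
  logi <- vapply(out, is.logical, TRUE)
  out[logi] <- lapply(out[logi], as.integer)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  digital <- grepl("^(laser[0-9]+_ttl|mask[0-9]+|ttl|mask|trigger)$", names(tr))
  tr[digital] <- lapply(tr[digital], function(x) x > 0.5)
  new_laser_trace(tr, rate_hz = NULL)
}

#' Read / write event CSV files
#'
#' Event lists use columns `t_ms`, `kind` (`trigger`, `prime`,
#' `prime_off`, `mock_on`, `mock_off`, `software_trigger`) and `line`.
#'
#' @param events An events tibble.
#' @param path File path.
#' @return `read_events()` returns an events tibble; `write_events()`
#'   returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  readr::write_csv(as_tibble(events), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          t_ms = readr::col_double(),
                          kind = readr::col_character(),
                          line = readr::col_integer()))
  validate_events(ev)
}
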