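#' Default calibration step schedule
#'
#' Control fractions at which the calibration routine emits its 10 s
#' pulses: ten equal steps from 10% to 100% of full scale.
#'
#' @return Numeric vector of fractions in (0, 1\].
#' @export
calib_steps_default <- function() {
  seq(0.1, 1, by = 0.1)
}

#' Fit a laser power calibration curve
#'
#' Ordinary least-squares linear fit of measured optical power (mW)
#' against the commanded control fraction, as entered from a power meter
#' during the stepped-intensity calibration routine. The fitted line maps
#' control fraction to mW and, inverted, lets stimulation power be
#' specified in mW. A negative intercept is allowed (lasers have a lasing
#' threshold).
#'
#' @param data A data frame with columns `fraction` (control fraction in
#'   \[0, 1\]) and `mW` (measured optical power). At least two distinct
#'   fractions are required.
#' @param laser_id Laser channel the curve belongs to.
#' @return An object of class `calibration_curve` with fields `laser_id`,
#'   `steps`, `measured_mW`, `slope` (mW per unit fraction), `intercept`
#'   (mW), `r2` and `created`.
#' @examples
#' d <- tibble::tibble(fraction = calib_steps_default(),
#'                     mW = 2 + 100 * calib_steps_default())
#' calib_fit(d)
#' @export
calib_fit <- function(data, laser_id = 1L) {
  data <- as_tibble(data)
  if (!all(c("fraction", "mW") %in% names(data))) {
    abort("`data` needs columns `fraction` and `mW`.",
          class = "optopulse_calib_error")
  }
  data <- dplyr::arrange(data, .data$fraction)
  x <- data$fraction
  y <- data$mW
  if (length(x) < 2) {
    abort("at least two calibration points are required.",
          class = "optopulse_calib_error")
  }
  if (anyDuplicated(x) || diff(range(x)) == 0) {
    abort("calibration steps must be distinct (zero variance in `fraction`).",
          class = "optopulse_calib_error")
  }
  fit <- lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(laser_id = as.integer(laser_id),
                 steps = x, measured_mW = y,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = r2,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> laser %d: mW = %.4g + %.4g * fraction (r2 = %.4f, %d points)\n",
              x$laser_id, x$intercept, x$slope, x$r2, length(x$steps)))
  invisible(x)
}

#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(laser_id = x$laser_id, slope = x$slope, intercept = x$intercept,
         r2 = x$r2, n = length(x$steps),
         mW_min = min(x$measured_mW), mW_max = max(x$measured_mW))
}

#' Convert a requested power in mW to a control fraction
#'
#' Inverts the calibration line: `(mW - intercept) / slope`. Requests
#' outside the measured power range are an error, not an extrapolation --
#' commanding an uncalibrated power at an animal is unsafe. A fraction
#' falling outside \[0, 1\] (possible with a negative intercept near
#' threshold) is clamped with a warning.
#'
#' @param curve A [calib_fit()] curve.
#' @param mW Requested optical power in mW.
#' @return Control fraction in \[0, 1\].
#' @export
mw_to_fraction <- function(curve, mW) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope == 0) {
    abort("calibration slope is zero or non-finite.",
          class = "optopulse_calib_error")
  }
  lo <- min(curve$measured_mW); hi <- max(curve$measured_mW)
  if (any(mW < lo - 1e-9) || any(mW > hi + 1e-9)) {
    abort(sprintf("requested power outside the calibrated range [%.4g, %.4g] mW.",
                  lo, hi),
          class = "optopulse_range_error")
  }
  frac <- (mW - curve$intercept) / curve$slope
  if (any(frac < 0) || any(frac > 1)) {
    warn("control fraction clamped to [0, 1].")
    frac <- pmin(1, pmax(0, frac))
  }
  frac
}

#' Convert a control fraction to the expected power in mW
#'
#' @param curve A [calib_fit()] curve.
#' @param fraction Control fraction(s).
#' @return Expected optical power in mW.
#' @export
fraction_to_mw <- function(curve, fraction) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$intercept + curve$slope * fraction
}

#' Check that a laser response is approximately linear
#'
#' The mW power scaling assumes a linear laser response; a curve whose
#' coefficient of determination falls below `r2_min` triggers a warning so
#' the operator can verify the laser before use.
#'
#' @param curve A [calib_fit()] curve.
#' @param r2_min Minimum acceptable r-squared (default 0.98).
#' @return `"pass"` or `"warn"` (invisibly); warns on `"warn"`.
#' @export
linearity_check <- function(curve, r2_min = 0.98) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$r2 < r2_min) {
    warn(sprintf("calibration r2 = %.4f is below %.4f: the laser response may not be linear.",
                 curve$r2, r2_min))
    return(invisible("warn"))
  }
  invisible("pass")
}

#' Persist / reload a calibration curve as JSON
#'
#' The curve is stored per laser as a JSON file and reloads
#' field-identical (full numeric precision).
#'
#' @param curve A [calib_fit()] curve.
#' @param path File path.
#' @return `read_calibration()` returns the curve;
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE,
                       digits = I(17))   # 17 significant digits: bit-exact
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(laser_id = as.integer(obj$laser_id),
                 steps = as.numeric(obj$steps),
                 measured_mW = as.numeric(obj$measured_mW),
                 slope = as.numeric(obj$slope),
                 intercept = as.numeric(obj$intercept),
                 r2 = as.numeric(obj$r2),
                 created = obj$created),
            class = "calibration_curve")
}
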