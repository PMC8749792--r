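#' Device calibration profile
#'
#' A calibration profile maps a device's unitless recorder amplitude `x`
#' (maximum absolute sample value since the last poll, modelled as an
#' integer in 0–32767) to a sound level in dB(C) through the logarithmic
#' model \deqn{y = a \cdot \log_{10}(x) + b,} where `a` is the slope in dB
#' per decade of amplitude and `b` the intercept in dB(C). The slope must be
#' positive (louder sound, larger amplitude).
#'
#' @param model_name Canonical device model name, e.g. `"Galaxy S7"`.
#' @param slope Slope `a` in dB per decade of amplitude; must be `> 0`.
#' @param intercept Intercept `b` in dB(C).
#' @param r_squared Coefficient of determination of the fit in `[0, 1]`, or
#'   `NA` for hand-entered / single-point profiles.
#' @param source Free-text provenance tag (e.g. `"experiment"`, `"offset"`).
#' @return An object of class `"device_calibration"`.
#' @examples
#' s7 <- device_calibration("Galaxy S7", 20.5379, 1.3481, 0.9995)
#' amplitude_to_db(1, s7)  # the intercept, 1.3481 dB(C)
#' @export
device_calibration <- function(model_name, slope, intercept,
                               r_squared = NA_real_, source = "manual") {
  stopifnot(is.character(model_name), length(model_name) == 1)
  slope <- as.numeric(slope); intercept <- as.numeric(intercept)
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be a positive finite number", call. = FALSE)
  }
  stopifnot(is.finite(intercept))
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(model_name = model_name, slope = slope, intercept = intercept,
         r_squared = as.numeric(r_squared), source = source),
    class = "device_calibration"
  )
}

#' @export
print.device_calibration <- function(x, ...) {
  cat(sprintf("<device_calibration> %s\n", x$model_name))
  cat(sprintf("  y = %.4f * log10(x) + %.4f  [dB(C)]\n", x$slope, x$intercept))
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname device_calibration
#' @param x A `device_calibration` object.
#' @param ... Unused.
#' @method tidy device_calibration
#' @export
tidy.device_calibration <- function(x, ...) {
  tibble::tibble(
    model_name = x$model_name, slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, source = x$source
  )
}

as_calibration <- function(cal) {
  if (inherits(cal, "device_calibration")) return(cal)
  if (inherits(cal, "calibration_fit")) return(cal$calibration)
  # one-row data frame (e.g. a registry row)
  if (is.data.frame(cal) && nrow(cal) == 1 &&
      all(c("model_name", "slope", "intercept") %in% names(cal))) {
    return(device_calibration(
      cal$model_name, cal$slope, cal$intercept,
      if ("r_squared" %in% names(cal)) cal$r_squared else NA_real_,
      if ("source" %in% names(cal)) cal$source else "registry"
    ))
  }
  stop("not a device calibration: supply a device_calibration, ",
       "a calibration_fit, or a one-row registry tibble", call. = FALSE)
}

#' Convert recorder amplitude to dB(C)
#'
#' Applies a device's calibration curve `y = a*log10(x) + b` to amplitude
#' values. Amplitudes below 1 are invalid (the logarithmic model is
#' undefined at 0 and the recorder emits non-negative integers); they raise
#' an error rather than being silently dropped.
#'
#' @param x Numeric vector of amplitudes, each `>= 1`.
#' @param cal A [device_calibration()], a [fit_log_calibration()] result, or
#'   a one-row registry tibble.
#' @return Numeric vector of levels in dB(C).
#' @examples
#' s7 <- device_calibration("Galaxy S7", 20.5379, 1.3481)
#' amplitude_to_db(c(1, 10, 100), s7)
#' @seealso [db_to_amplitude()] for the inverse.
#' @export
amplitude_to_db <- function(x, cal) {
  cal <- as_calibration(cal)
  stopifnot(is.numeric(x))
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("amplitude must be positive and finite for dB conversion",
         call. = FALSE)
  }
  cal$slope * log10(x) + cal$intercept
}

#' Convert dB(C) back to recorder amplitude
#'
#' Inverts the calibration curve: `x = 10^((L - b) / a)`. Round trips with
#' [amplitude_to_db()] to within 1e-9 dB.
#'
#' @param level_db Numeric vector of levels in dB(C).
#' @inheritParams amplitude_to_db
#' @return Numeric vector of (continuous, not integer-rounded) amplitudes.
#' @examples
#' s7 <- device_calibration("Galaxy S7", 20.5379, 1.3481)
#' db_to_amplitude(50, s7)  # about 233.8
#' @export
db_to_amplitude <- function(level_db, cal) {
  cal <- as_calibration(cal)
  level_db <- as.numeric(level_db)
  stopifnot(all(is.finite(level_db)))
  10^((level_db - cal$intercept) / cal$slope)
}

#' Fit a logarithmic calibration curve to a calibration session
#'
#' A calibration session pairs reference levels read off a calibrated sound
#' level meter with the amplitude the device reported for the same tone
#' (1000 Hz pure tone, C-weighting; a standard session holds seven points at
#' 50–80 dB(C) in 5 dB steps). The model `level = a*log10(amplitude) + b`
#' is fitted by ordinary least squares with the dB level as response, which
#' reproduces the reported per-device equations and their coefficient of
#' determination.
#'
#' @param data Data frame of calibration points.
#' @param level,amplitude Columns of `data` holding the reference level in
#'   dB(C) and the device amplitude (tidy-eval; defaults `reference_db`,
#'   `amplitude`). At least two points with distinct positive amplitudes
#'   are required.
#' @param model_name Model name recorded on the resulting profile.
#' @return An object of class `"calibration_fit"` with components
#'   `calibration` (a [device_calibration()]), `fit` (the underlying `lm`),
#'   and `data` (the points used). Supports [tidy()], [glance()],
#'   [ggplot2::autoplot()] and `predict()`.
#' @examples
#' pts <- tibble::tibble(reference_db = seq(50, 80, 5),
#'                       amplitude = 10^((reference_db - 1.35) / 20.54))
#' fit <- fit_log_calibration(pts, model_name = "demo")
#' glance(fit)
#' @export
fit_log_calibration <- function(data, level = reference_db,
                                amplitude = amplitude,
                                model_name = "unnamed device") {
  pts <- dplyr::transmute(
    data,
    reference_db = as.numeric({{ level }}),
    amplitude = as.numeric({{ amplitude }})
  )
  if (any(!is.finite(pts$amplitude)) || any(pts$amplitude <= 0)) {
    stop("calibration amplitudes must be positive", call. = FALSE)
  }
  if (nrow(pts) < 2 || dplyr::n_distinct(pts$amplitude) < 2) {
    stop("need at least two points with distinct amplitudes to fit a ",
         "calibration curve", call. = FALSE)
  }
  fit <- stats::lm(reference_db ~ log10(amplitude), data = pts)
  # R^2 computed directly: summary.lm warns on exact (noiseless) fits
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((pts$reference_db - mean(pts$reference_db))^2)
  r2 <- 1 - ss_res / ss_tot
  cal <- device_calibration(
    model_name,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2, source = "fit"
  )
  structure(list(calibration = cal, fit = fit, data = pts),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> %d points\n", nrow(x$data)))
  print(x$calibration)
  invisible(x)
}

#' @rdname fit_log_calibration
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @method tidy calibration_fit
#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$calibration$intercept, x$calibration$slope),
    std.error = unname(suppressWarnings(
      summary(x$fit)$coefficients[, "Std. Error"]))
  )
}

#' @rdname fit_log_calibration
#' @method glance calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    model_name = x$calibration$model_name,
    slope = x$calibration$slope,
    intercept = x$calibration$intercept,
    r.squared = x$calibration$r_squared,
    sigma = suppressWarnings(summary(x$fit)$sigma),
    nobs = nrow(x$data)
  )
}

#' @export
predict.calibration_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  amplitude_to_db(newdata$amplitude, object$calibration)
}

#' Single-point offset calibration
#'
#' The fitted calibration curves of different device models share nearly
#' identical slopes and differ mainly by an offset, so an additional device
#' can be approximately calibrated from a single reference measurement:
#' keep a reference slope and solve for the intercept,
#' `b = level - slope * log10(amplitude)`. No `r_squared` is attached —
#' a one-point profile has no goodness of fit.
#'
#' @param level_db Reference level in dB(C) at which the point was taken.
#' @param amplitude Device amplitude observed at that level; must be `> 0`.
#' @param reference_slope Slope in dB per decade borrowed from a fully
#'   calibrated device.
#' @param model_name Model name recorded on the profile.
#' @return A [device_calibration()] with `r_squared = NA`.
#' @examples
#' offset_calibration(65, 1000, reference_slope = 21)  # intercept 2
#' @export
offset_calibration <- function(level_db, amplitude, reference_slope,
                               model_name = "offset-calibrated device") {
  stopifnot(length(level_db) == 1, length(amplitude) == 1)
  if (!is.finite(amplitude) || amplitude <= 0) {
    stop("calibration amplitude must be positive", call. = FALSE)
  }
  device_calibration(
    model_name, slope = reference_slope,
    intercept = level_db - reference_slope * log10(amplitude),
    r_squared = NA_real_, source = "offset"
  )
}
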