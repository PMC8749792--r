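# Reference sound pressure for SPL: p0 = 20 uPa.
P_REF_PA <- 2e-5

#' Reference sound pressure
#'
#' The standard airborne reference pressure \eqn{p_0 = 20\,\mu}Pa used in the
#' definition of sound pressure level.
#'
#' @return Reference pressure in pascal (a length-one numeric).
#' @export
reference_pressure <- function() P_REF_PA

#' Tag a vector of decibel values with a frequency weighting
#'
#' Sound levels in this package are plain numeric decibel values optionally
#' tagged with the frequency weighting they were measured under: `"C"`,
#' `"A"`, or `"SPL"` (unweighted). The tag is metadata only — no filter
#' curves are applied. At 1000 Hz the A- and C-weighting curves apply zero
#' offset, so all three tags denote the same physical level there; the
#' calibration experiments this package models are fixed at 1000 Hz.
#'
#' @param value Numeric vector of levels in dB.
#' @param weighting One of `"C"`, `"A"`, `"SPL"`.
#' @return A numeric vector of class `"sound_level"` carrying a `weighting`
#'   attribute.
#' @examples
#' sound_level(c(50, 65, 80), "C")
#' @export
sound_level <- function(value, weighting = c("C", "A", "SPL")) {
  weighting <- match.arg(weighting)
  stopifnot(is.numeric(value), all(is.finite(value)))
  structure(as.numeric(value), weighting = weighting, class = "sound_level")
}

#' @export
print.sound_level <- function(x, ...) {
  cat(format(unclass(x), ...), paste0("dB(", attr(x, "weighting"), ")"), "\n")
  invisible(x)
}

db_weighting <- function(x) {
  w <- attr(x, "weighting", exact = TRUE)
  if (is.null(w)) NA_character_ else w
}

#' Sound pressure level from pressure
#'
#' Converts a root-mean-square sound pressure in pascal to sound pressure
#' level, \eqn{L_p = 20 \log_{10}(p / p_0)} dB with \eqn{p_0 = 20\,\mu}Pa.
#'
#' @param p Numeric vector of pressures in Pa; must be strictly positive.
#' @return Numeric vector of levels in dB SPL.
#' @examples
#' spl_from_pressure(2e-5)  # 0 dB at the reference pressure
#' spl_from_pressure(0.2)   # four decades above p0 -> 80 dB
#' @seealso [pressure_from_spl()]
#' @export
spl_from_pressure <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("sound pressure must be strictly positive and finite", call. = FALSE)
  }
  20 * log10(p / P_REF_PA)
}

#' Sound pressure from sound pressure level
#'
#' Inverse of [spl_from_pressure()]: \eqn{p = p_0 \cdot 10^{L/20}}.
#'
#' @param level_db Numeric vector of levels in dB SPL (finite).
#' @return Numeric vector of pressures in Pa.
#' @examples
#' pressure_from_spl(94)  # about 1.002 Pa
#' @export
pressure_from_spl <- function(level_db) {
  level_db <- as.numeric(level_db)
  stopifnot(all(is.finite(level_db)))
  P_REF_PA * 10^(level_db / 20)
}

#' Energetic (equivalent-continuous) mean of sound levels
#'
#' Decibel values are logarithmic and cannot be averaged arithmetically:
#' they must be transformed back to their energetic source values first.
#' For equal-duration samples the equivalent continuous level is
#' \deqn{L_{eq} = 10 \log_{10}\left(\frac{1}{N}\sum_i 10^{L_i/10}\right).}
#' This always lies at or above the arithmetic mean of the `L_i` (Jensen's
#' inequality; `10^(x/10)` is convex), with equality only when all levels
#' are equal — the root cause of the legacy averaging bias this package
#' audits.
#'
#' @param level_db Numeric vector of levels in dB (non-empty), a
#'   [sound_level()] vector, or a list of `sound_level` vectors. A list whose
#'   elements carry different weighting tags is an error: levels under
#'   different frequency weightings are not energetically commensurable.
#' @return The equivalent continuous level, a length-one numeric (tagged
#'   `sound_level` when the input was tagged).
#' @examples
#' energetic_mean_db(c(60, 60, 60))          # 60
#' energetic_mean_db(c(rep(50, 29), 80))     # 65.35, not the arithmetic 51
#' @export
energetic_mean_db <- function(level_db) {
  weighting <- NULL
  if (is.list(level_db)) {
    tags <- unique(vapply(level_db, db_weighting, character(1)))
    if (length(tags) > 1) {
      stop("cannot average levels with mixed weighting tags: ",
           paste(tags, collapse = ", "), call. = FALSE)
    }
    if (!is.na(tags)) weighting <- tags
    level_db <- unlist(lapply(level_db, unclass))
  } else if (inherits(level_db, "sound_level")) {
    weighting <- db_weighting(level_db)
    level_db <- unclass(level_db)
  }
  if (length(level_db) == 0) {
    stop("cannot average an empty set of levels", call. = FALSE)
  }
  stopifnot(is.numeric(level_db), all(is.finite(level_db)))
  out <- 10 * log10(mean(10^(level_db / 10)))
  if (!is.null(weighting)) out <- sound_level(out, weighting)
  out
}

#' Round a decibel value for display
#'
#' Rounds half-up to 0.1 dB (the resolution of a class-2 sound level meter).
#' Internal computations keep full precision; rounding belongs only at the
#' presentation layer.
#'
#' @param level_db Numeric vector of levels in dB.
#' @param digits Decimal digits to keep (default 1).
#' @return Rounded numeric vector.
#' @examples
#' round_db(55.86286)  # 55.9
#' @export
round_db <- function(level_db, digits = 1) {
  scale <- 10^digits
  sign(level_db) * floor(abs(level_db) * scale + 0.5) / scale
}
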