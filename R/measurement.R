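#' A single 15-second amplitude measurement
#'
#' The mobile app polls the recorder's maximum absolute amplitude every
#' 500 ms for 15 s, giving 30 integer samples per measurement. The first
#' two samples are unreliable on several handsets (the first is
#' consistently 0, the second depressed) and are discarded by the
#' corrected pipeline; `n_discard` records how many leading samples a
#' consumer should drop (0 or 2).
#'
#' @param samples Numeric vector of non-negative amplitude samples.
#'   Nonstandard lengths (other than 30) are accepted with a warning,
#'   since deployments differ in effective sample count.
#' @param device_id Optional device ID the series came from.
#' @param n_discard Number of leading startup samples to discard in
#'   corrected averaging; 0 or 2 (default 2).
#' @return An object of class `"amplitude_series"`.
#' @examples
#' s <- amplitude_series(c(0, 120, rep(400, 28)))
#' legacy_average(s)
#' @export
amplitude_series <- function(samples, device_id = NA_character_,
                             n_discard = 2L) {
  samples <- as.numeric(samples)
  stopifnot(all(is.finite(samples)))
  if (any(samples < 0)) {
    stop("amplitude samples must be non-negative", call. = FALSE)
  }
  if (!n_discard %in% c(0L, 2L)) {
    stop("n_discard must be 0 or 2", call. = FALSE)
  }
  if (length(samples) != 30) {
    warning("amplitude series has ", length(samples),
            " samples; the standard measurement has 30", call. = FALSE)
  }
  structure(list(samples = samples, device_id = as.character(device_id),
                 n_discard = as.integer(n_discard)),
            class = "amplitude_series")
}

#' @export
print.amplitude_series <- function(x, ...) {
  cat(sprintf("<amplitude_series> %d samples (discard first %d)%s\n",
              length(x$samples), x$n_discard,
              if (is.na(x$device_id)) "" else paste0(" [", x$device_id, "]")))
  print(x$samples)
  invisible(x)
}

series_samples <- function(series) {
  if (inherits(series, "amplitude_series")) series$samples
  else as.numeric(series)
}

series_discard <- function(series, default = 2L) {
  if (inherits(series, "amplitude_series")) series$n_discard else default
}

#' Legacy stored average of an amplitude series
#'
#' The deployed app arithmetically averaged all 30 raw amplitude samples —
#' startup artifacts included — and stored that single number in the
#' database. That calculation is wrong for sound levels (they are
#' logarithmic and must be averaged energetically), but it is exactly what
#' the stored values contain, so it is reproduced here verbatim for
#' auditing.
#'
#' @param series An [amplitude_series()] or numeric vector of samples.
#' @return The arithmetic mean amplitude as stored (length-one numeric).
#' @examples
#' legacy_average(rep(500, 30))               # 500
#' legacy_average(c(rep(233.8, 29), 6751.8))  # 451.07
#' @seealso [corrected_average()] for the right way.
#' @export
legacy_average <- function(series) {
  x <- series_samples(series)
  if (length(x) == 0) stop("empty amplitude series", call. = FALSE)
  mean(x)
}

#' Corrected (energetic) average of an amplitude series
#'
#' The corrected measurement pipeline: drop the leading startup samples,
#' convert each retained amplitude to dB(C) through the device's
#' calibration curve, and take the energetic (equivalent-continuous) mean
#' of those levels. Retained samples below 1 cannot be converted (the
#' logarithmic curve is undefined there) and raise an error naming the
#' offending sample indices.
#'
#' @param series An [amplitude_series()] or numeric vector of samples.
#' @param cal Device calibration (see [amplitude_to_db()]).
#' @param n_discard Leading samples to drop; defaults to the series' own
#'   `n_discard` (2 for a plain numeric vector).
#' @return The equivalent continuous level in dB(C) (length-one numeric).
#' @examples
#' s7 <- device_calibration("Galaxy S7", 20.5379, 1.3481)
#' corrected_average(rep(234, 30), s7)
#' @export
corrected_average <- function(series, cal, n_discard = series_discard(series)) {
  x <- series_samples(series)
  if (length(x) <= n_discard) {
    stop("series must have more than n_discard samples", call. = FALSE)
  }
  retained <- if (n_discard > 0) x[-seq_len(n_discard)] else x
  bad <- which(retained < 1)
  if (length(bad) > 0) {
    stop("retained samples below 1 cannot be converted to dB ",
         "(sample indices after discard: ", paste(bad, collapse = ", "), ")",
         call. = FALSE)
  }
  energetic_mean_db(amplitude_to_db(retained, cal))
}

#' Detect the recorder startup artifact in a series
#'
#' Several handsets report a first amplitude of exactly 0 and a depressed
#' second amplitude within the first second of recording. This check flags
#' (i) a zero first sample and (ii) a second sample below half the median
#' of samples 3 onwards. It only flags — repairs are left to the discard
#' rule in [corrected_average()].
#'
#' @param series An [amplitude_series()] or numeric vector of samples.
#' @return A one-row tibble: `first_sample_zero`, `second_sample_low`,
#'   `any_artifact`, and `flagged_indices` (list column of 1-based sample
#'   indices).
#' @examples
#' detect_startup_artifact(c(0, 100, rep(400, 28)))
#' @export
detect_startup_artifact <- function(series) {
  x <- series_samples(series)
  first_zero <- length(x) >= 1 && x[1] == 0
  second_low <- FALSE
  if (length(x) >= 3) {
    steady <- stats::median(x[3:length(x)])
    second_low <- x[2] < steady / 2
  }
  idx <- c(if (first_zero) 1L, if (second_low) 2L)
  tibble::tibble(
    first_sample_zero = first_zero,
    second_sample_low = second_low,
    any_artifact = first_zero || second_low,
    flagged_indices = list(as.integer(idx))
  )
}

#' Read raw amplitude series from CSV
#'
#' Reads the long per-sample format `entry_id, device_id, sample_index
#' (0-based), amplitude` and nests each measurement into an
#' [amplitude_series()].
#'
#' @param path CSV file path.
#' @param n_discard Discard count applied to every series.
#' @return A tibble with one row per entry: `entry_id`, `device_id`, and a
#'   `series` list column of `amplitude_series`.
#' @export
read_series_csv <- function(path, n_discard = 2L) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    entry_id = readr::col_character(),
    device_id = readr::col_character(),
    sample_index = readr::col_integer(),
    amplitude = readr::col_double()
  ))
  raw |>
    dplyr::arrange(entry_id, sample_index) |>
    dplyr::group_by(entry_id, device_id) |>
    dplyr::summarise(
      series = list(amplitude_series(amplitude, device_id = device_id[1],
                                     n_discard = n_discard)),
      .groups = "drop"
    )
}
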