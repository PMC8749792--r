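#' Worst-case legacy averaging error for one device
#'
#' Quantifies the bias of the legacy stored average in its worst observed
#' shape: a measurement whose samples are quiet except for one loud burst.
#' Amplitudes are reconstructed by inverting the device's calibration
#' curve at the low and high levels (the raw experimental amplitudes are
#' not available, so the fitted curve stands in for them; this reproduces
#' the calibrated worst case exactly for the device whose curve fits its
#' measurements best and to within a few tenths of a dB for the others).
#' The legacy pathway arithmetically averages the amplitude composition
#' and converts the mean; the correct pathway converts each sample and
#' takes the energetic mean of the levels. The difference is how much the
#' stored value understates the actual loudness.
#'
#' @param cal Device calibration (see [amplitude_to_db()]).
#' @param low_level,high_level Quiet and loud levels in dB(C); defaults 50
#'   and 80, the bounds of the calibration experiment.
#' @param n_total Samples per measurement (default 30).
#' @param n_high How many samples sit at the loud level (default 1).
#' @param round_amplitudes Round reconstructed amplitudes to integers as
#'   the recorder would (changes results by under 0.05 dB); default off.
#' @return A one-row tibble: `model_name`, `legacy_db`, `correct_db`,
#'   `difference` (correct minus legacy, always `>= 0`), all full
#'   precision.
#' @examples
#' worst_case_error(registry_calibration("Galaxy S7"))
#' @export
worst_case_error <- function(cal, low_level = 50, high_level = 80,
                             n_total = 30L, n_high = 1L,
                             round_amplitudes = FALSE) {
  cal <- as_calibration(cal)
  stopifnot(n_high >= 0, n_high < n_total, low_level <= high_level)
  x_low <- db_to_amplitude(low_level, cal)
  x_high <- db_to_amplitude(high_level, cal)
  if (round_amplitudes) {
    x_low <- round(x_low); x_high <- round(x_high)
  }
  amps <- c(rep(x_low, n_total - n_high), rep(x_high, n_high))
  legacy <- amplitude_to_db(mean(amps), cal)
  correct <- energetic_mean_db(amplitude_to_db(amps, cal))
  tibble::tibble(
    model_name = cal$model_name,
    legacy_db = legacy,
    correct_db = correct,
    difference = correct - legacy
  )
}

#' Worst-case error table across a registry
#'
#' Runs [worst_case_error()] for every calibrated device model in a
#' registry. Display columns rounded to 0.1 dB are included alongside the
#' full-precision values.
#'
#' @param registry Registry tibble (see [default_registry()]).
#' @inheritParams worst_case_error
#' @return A tibble with one row per calibrated model: the full-precision
#'   `legacy_db`, `correct_db`, `difference` plus `legacy_db_disp`,
#'   `correct_db_disp`, `difference_disp` rounded to 0.1 dB.
#' @examples
#' error_table()
#' @export
error_table <- function(registry = default_registry(), low_level = 50,
                        high_level = 80, n_total = 30L, n_high = 1L,
                        round_amplitudes = FALSE) {
  cals <- registry |>
    dplyr::filter(calibrated, device_id == canonical_id)
  if (nrow(cals) == 0) {
    return(tibble::tibble(
      device_id = character(), model_name = character(),
      legacy_db = numeric(), correct_db = numeric(), difference = numeric(),
      legacy_db_disp = numeric(), correct_db_disp = numeric(),
      difference_disp = numeric()
    ))
  }
  rows <- purrr::map2_dfr(
    cals$device_id, seq_len(nrow(cals)),
    function(id, i) {
      res <- worst_case_error(cals[i, ], low_level, high_level,
                              n_total, n_high, round_amplitudes)
      dplyr::bind_cols(tibble::tibble(device_id = id), res)
    }
  )
  dplyr::mutate(
    rows,
    legacy_db_disp = round_db(legacy_db),
    correct_db_disp = round_db(correct_db),
    difference_disp = round_db(correct_db_disp - legacy_db_disp)
  )
}

#' Plot the legacy-vs-correct worst-case comparison
#'
#' Dumbbell-style plot of legacy and correct levels per device model from
#' an [error_table()].
#'
#' @param errors Tibble from [error_table()].
#' @return A ggplot object.
#' @export
plot_error_table <- function(errors = error_table()) {
  long <- tidyr::pivot_longer(
    errors, c("legacy_db", "correct_db"),
    names_to = "pathway", values_to = "level_db"
  ) |>
    dplyr::mutate(pathway = dplyr::recode(pathway,
                                          legacy_db = "legacy (stored)",
                                          correct_db = "correct (Leq)"))
  ggplot2::ggplot(long, ggplot2::aes(x = level_db, y = model_name)) +
    ggplot2::geom_line(ggplot2::aes(group = model_name), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = pathway), size = 3) +
    ggplot2::labs(x = "worst-case measurement level [dB(C)]", y = NULL,
                  colour = NULL,
                  title = "Understatement of loudness by the legacy average") +
    ggplot2::theme_minimal()
}
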