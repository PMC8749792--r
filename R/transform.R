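#' Transform stored amplitude entries to dB(C)
#'
#' Converts the stored per-questionnaire amplitude averages of a
#' crowdsensed entry table into (partially) comparable dB(C) values using
#' the device registry. Every input entry appears exactly once in the
#' output with a `status` explaining what happened to it — nothing is
#' silently dropped:
#'
#' * `converted` — android entry, known calibration, amplitude >= 1;
#'   `db_c` holds the calibrated level.
#' * `no_calibration` — android entry on a device with no calibration
#'   profile (or an unknown device ID).
#' * `invalid_amplitude` — android entry whose stored amplitude is below 1
#'   (the logarithmic curve is undefined there) or missing.
#' * `non_android` — iOS and unknown-platform entries (the stored iOS
#'   relative-dB values are not comparable and are not converted).
#'
#' Converted levels outside the calibrated range are flagged
#' `extrapolated`: the curves were fitted between `range_low` and
#' `range_high` dB(C) and are applied, not trusted, outside it. Stored
#' values also inherit the legacy averaging bias (they can understate the
#' measured loudness by up to roughly 9–10 dB) and were captured through a
#' narrowband voice codec; `db_c` is comparable across devices, not a
#' reference-grade level.
#'
#' @param entries Data frame of sound entries with columns `entry_id`,
#'   `user_id`, `device_id`, `platform` (`"android"`, `"ios"`,
#'   `"unknown"`), `timestamp`, `stored_amplitude`, and optionally
#'   `tinnitus_loudness`.
#' @param registry Registry tibble (see [default_registry()]).
#' @param range_low,range_high Calibrated range in dB(C) outside which
#'   converted values are flagged extrapolated (defaults 50 and 80).
#' @return A tibble of the input entries plus `model_name`, `db_c`,
#'   `status` and `extrapolated`.
#' @examples
#' entries <- tibble::tibble(
#'   entry_id = "e1", user_id = "u1", device_id = "SM-G930F",
#'   platform = "android", timestamp = "2020-01-01T12:00:00Z",
#'   stored_amplitude = 500
#' )
#' transform_entries(entries)
#' @export
transform_entries <- function(entries, registry = default_registry(),
                              range_low = 50, range_high = 80) {
  stopifnot(all(c("entry_id", "user_id", "platform") %in% names(entries)))
  entries <- tibble::as_tibble(entries)
  if (!"device_id" %in% names(entries)) entries$device_id <- NA_character_
  if (!"stored_amplitude" %in% names(entries)) {
    entries$stored_amplitude <- NA_real_
  }
  res <- resolve_device(entries$device_id, registry)
  out <- entries |>
    dplyr::mutate(
      model_name = ifelse(is.na(device_id), NA_character_, res$model_name),
      .calibrated = res$calibrated,
      status = dplyr::case_when(
        platform != "android" ~ "non_android",
        !.calibrated ~ "no_calibration",
        is.na(stored_amplitude) | stored_amplitude < 1 ~ "invalid_amplitude",
        TRUE ~ "converted"
      ),
      db_c = ifelse(status == "converted",
                    res$slope * log10(stored_amplitude) + res$intercept,
                    NA_real_),
      extrapolated = status == "converted" &
        (db_c < range_low | db_c > range_high)
    ) |>
    dplyr::select(-".calibrated")
  out
}

#' Per-model summary of converted sound levels
#'
#' Summarises the `converted` entries of [transform_entries()] output per
#' canonical device model: minimum, maximum and arithmetic mean of the
#' dB(C) values, plus the energetic (equivalent-continuous) mean. The
#' arithmetic mean of levels has no clean acoustic meaning but is the
#' conventional per-entry summary; the energetic mean is the loudness-
#' faithful one, and is never below the arithmetic mean. Both are reported
#' so the choice stays visible.
#'
#' @param transformed Tibble from [transform_entries()].
#' @return A tibble per model: `model_name`, `n`, `min_db`, `max_db`,
#'   `avg_db` (arithmetic), `energetic_avg_db`, sorted by descending `n`.
#' @export
summarize_levels <- function(transformed) {
  transformed |>
    dplyr::filter(status == "converted") |>
    dplyr::group_by(model_name) |>
    dplyr::summarise(
      n = dplyr::n(),
      min_db = min(db_c),
      max_db = max(db_c),
      avg_db = mean(db_c),
      energetic_avg_db = energetic_mean_db(db_c),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(n))
}

#' Dataset composition report
#'
#' Describes a crowdsensed entry table the way platform datasets are
#' conventionally reported: per-platform entry counts with percentage
#' shares (rounded half-up to two decimals), and per canonical device
#' model the number of distinct users, the measurement count, and
#' measurements per user rounded to the nearest integer, sorted descending
#' by measurement count.
#'
#' @param entries Data frame of sound entries (see [transform_entries()]).
#' @param registry Registry tibble used to canonicalise device IDs into
#'   model names (alias groups merge).
#' @return A list of class `"composition_report"` with tibbles `platforms`
#'   (`platform`, `n`, `share_pct`) and `models` (`model_name`, `n_users`,
#'   `n_measurements`, `per_user`).
#' @examples
#' db <- generate_synthetic_database(database_spec(
#'   models = tibble::tibble(model_name = "Galaxy S7", n_users = 3,
#'                           n_measurements = 30),
#'   seed = 1))
#' dataset_composition(db)
#' @export
dataset_composition <- function(entries, registry = default_registry()) {
  entries <- tibble::as_tibble(entries)
  n_total <- nrow(entries)
  platforms <- entries |>
    dplyr::count(platform = factor(platform,
                                   c("android", "ios", "unknown"))) |>
    tidyr::complete(platform, fill = list(n = 0L)) |>
    dplyr::mutate(
      platform = as.character(platform),
      share_pct = if (n_total == 0) 0 else round_half_up(100 * n / n_total, 2)
    )
  android <- dplyr::filter(entries, platform == "android", !is.na(device_id))
  if (nrow(android) == 0) {
    models <- tibble::tibble(model_name = character(), n_users = integer(),
                             n_measurements = integer(), per_user = numeric())
  } else {
    models <- android |>
      dplyr::mutate(model_name = resolve_device(device_id,
                                                registry)$model_name) |>
      dplyr::group_by(model_name) |>
      dplyr::summarise(
        n_users = dplyr::n_distinct(user_id),
        n_measurements = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::mutate(per_user = round_half_up(n_measurements / n_users, 0)) |>
      dplyr::arrange(dplyr::desc(n_measurements))
  }
  structure(list(platforms = platforms, models = models, n_total = n_total),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("<composition_report> %d entries\n\nPlatforms:\n", x$n_total))
  print(x$platforms)
  cat("\nDevice models (descending by measurements):\n")
  print(x$models, n = 30)
  invisible(x)
}

round_half_up <- function(x, digits) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Per-user plausibility screen
#'
#' Screens users for inclusion in longitudinal sound/symptom analyses: a
#' user is eligible when they contributed more than `min_entries` sound
#' measurements and both their reported symptom loudness and their stored
#' amplitudes fluctuate plausibly (not all zero, not constant). Constant
#' or all-zero streams usually mean a muted microphone, a permission
#' problem or disengaged reporting.
#'
#' @param entries Data frame of sound entries (see [transform_entries()]).
#' @param min_entries Minimum entry count, exclusive (default 500).
#' @return A tibble per user: `user_id`, `n_entries`, flags
#'   `loudness_all_zero`, `loudness_constant`, `amplitude_all_zero`,
#'   `amplitude_constant`, and `eligible`.
#' @export
plausibility_screen <- function(entries, min_entries = 500) {
  entries <- tibble::as_tibble(entries)
  if (!"tinnitus_loudness" %in% names(entries)) {
    entries$tinnitus_loudness <- NA_real_
  }
  if (!"stored_amplitude" %in% names(entries)) {
    entries$stored_amplitude <- NA_real_
  }
  all_zero <- function(v) length(v) > 0 && all(!is.na(v)) && all(v == 0)
  constant <- function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && dplyr::n_distinct(v) == 1
  }
  entries |>
    dplyr::group_by(user_id) |>
    dplyr::summarise(
      n_entries = dplyr::n(),
      loudness_all_zero = all_zero(tinnitus_loudness),
      loudness_constant = constant(tinnitus_loudness),
      amplitude_all_zero = all_zero(stored_amplitude),
      amplitude_constant = constant(stored_amplitude),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      eligible = n_entries > min_entries &
        !loudness_all_zero & !loudness_constant &
        !amplitude_all_zero & !amplitude_constant
    )
}

#' Read / write sound entry tables
#'
#' CSV round trip for the entry table format: comma-separated, header row,
#' UTF-8, columns `entry_id, user_id, device_id, platform, timestamp,
#' stored_amplitude, tinnitus_loudness`.
#'
#' @param path CSV file path.
#' @return `read_entries_csv()` returns a tibble of entries;
#'   `write_entries_csv()` returns `path` invisibly.
#' @export
read_entries_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    entry_id = readr::col_character(),
    user_id = readr::col_character(),
    device_id = readr::col_character(),
    platform = readr::col_character(),
    timestamp = readr::col_character(),
    stored_amplitude = readr::col_double(),
    tinnitus_loudness = readr::col_double()
  ))
}

#' @rdname read_entries_csv
#' @param entries Tibble of entries to write.
#' @export
write_entries_csv <- function(entries, path) {
  readr::write_csv(entries, path)
  invisible(path)
}
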