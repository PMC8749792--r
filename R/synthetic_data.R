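# Vectorised core shared by simulate_series() and the database generator.
# Returns an n_samples x n matrix of amplitude samples for n true levels.
simulate_amplitude_matrix <- function(true_levels, cal, sigma_db = 0.5,
                                      startup_artifact = TRUE,
                                      clip_max = 32767, n_samples = 30L,
                                      integer_samples = TRUE) {
  cal <- as_calibration(cal)
  n <- length(true_levels)
  n_retained <- n_samples - if (startup_artifact) 2L else 0L
  eps <- matrix(stats::rnorm(n_retained * n, 0, sigma_db), n_retained, n)
  amps <- db_to_amplitude(rep(true_levels, each = n_retained) + as.vector(eps),
                          cal)
  amps <- matrix(amps, n_retained, n)
  if (integer_samples) amps <- round(amps)
  amps <- pmin(pmax(amps, 0), clip_max)
  if (!startup_artifact) return(amps)
  u <- stats::runif(n)
  second <- u * amps[1, ]
  if (integer_samples) second <- floor(second)
  rbind(matrix(0, 1, n), matrix(second, 1, n), amps)
}

#' Simulate one smartphone amplitude measurement
#'
#' Generates a 15 s measurement (30 samples at 500 ms) as a device with a
#' known calibration curve would record a steady tone: each retained
#' sample is the curve-inverted amplitude of `true_level` plus Gaussian
#' dB noise (multiplicative microphone gain error — additive in dB,
#' log-normal in amplitude), rounded to an integer and clipped to the
#' recorder range. With `startup_artifact = TRUE` (the empirically
#' observed behaviour) the first sample is 0 and the second a uniform
#' fraction in `[0, 1)` of the third.
#'
#' @param true_level True steady sound level in dB(C).
#' @param cal Device calibration (see [amplitude_to_db()]).
#' @param sigma_db Standard deviation of the per-sample dB noise
#'   (default 0.5).
#' @param startup_artifact Inject the zero/depressed first two samples
#'   (default `TRUE`).
#' @param clip_max Amplitude ceiling of the recorder (default 32767).
#' @param n_samples Samples per measurement (default 30).
#' @param integer_samples Round samples to integers as the recorder does
#'   (default `TRUE`).
#' @param seed Optional integer seed; the same seed gives an identical
#'   series and the caller's RNG state is left untouched.
#' @return An [amplitude_series()] (with `n_discard = 2`).
#' @examples
#' s7 <- registry_calibration("Galaxy S7")
#' simulate_series(50, s7, sigma_db = 0, seed = 1)
#' @export
simulate_series <- function(true_level, cal, sigma_db = 0.5,
                            startup_artifact = TRUE, clip_max = 32767,
                            n_samples = 30L, integer_samples = TRUE,
                            seed = NULL) {
  stopifnot(length(true_level) == 1, is.finite(true_level), sigma_db >= 0,
            clip_max > 0)
  run <- function() {
    simulate_amplitude_matrix(true_level, cal, sigma_db, startup_artifact,
                              clip_max, n_samples, integer_samples)[, 1]
  }
  samples <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  cal <- as_calibration(cal)
  amplitude_series(samples, device_id = cal$model_name, n_discard = 2L)
}

#' Simulate a full calibration session
#'
#' Emulates the bench calibration procedure: for each reference level a
#' steady 1000 Hz tone is "played", the device records a measurement, and
#' the session stores the amplitude recovered from the corrected
#' (discard-two, energetic) average of that measurement. Defaults follow
#' the standard protocol of seven levels from 50 to 80 dB(C) in 5 dB
#' steps. Samples are kept continuous by default so that a noiseless
#' session lies exactly on the calibration curve; set
#' `integer_samples = TRUE` for recorder-faithful integer quantisation.
#'
#' @param cal Device calibration used as ground truth.
#' @param levels Reference levels in dB(C) (default `seq(50, 80, 5)`).
#' @inheritParams simulate_series
#' @return A tibble of calibration points (`reference_db`, `amplitude`)
#'   ready for [fit_log_calibration()].
#' @examples
#' s7 <- registry_calibration("Galaxy S7")
#' sess <- generate_calibration_session(s7, sigma_db = 0, seed = 1)
#' fit_log_calibration(sess)
#' @export
generate_calibration_session <- function(cal, levels = seq(50, 80, by = 5),
                                         sigma_db = 0.5,
                                         startup_artifact = TRUE,
                                         clip_max = 32767,
                                         integer_samples = FALSE,
                                         seed = NULL) {
  stopifnot(length(levels) >= 1)
  cal <- as_calibration(cal)
  run <- function() {
    purrr::map_dbl(levels, function(L) {
      s <- simulate_series(L, cal, sigma_db, startup_artifact, clip_max,
                           integer_samples = integer_samples)
      db_to_amplitude(corrected_average(s, cal), cal)
    })
  }
  amps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(reference_db = as.numeric(levels), amplitude = amps)
}

#' Specification for a synthetic crowdsensed database
#'
#' Describes the shape of a synthetic entry table: which device models
#' contribute how many users and measurements, the per-platform entry
#' counts, and the latent processes behind symptom loudness and true
#' environmental level. The generator is a pure function of this spec —
#' the same spec (including its mandatory seed) always yields the same
#' database.
#'
#' @param models Data frame with columns `model_name`, `n_users`,
#'   `n_measurements` (one row per android device model). A model with
#'   more users than measurements is an error.
#' @param n_ios,n_unknown Entry counts for the iOS platform and for
#'   entries without user-agent information (default 0).
#' @param n_android Total android entry count; defaults to the sum over
#'   `models`. Any excess over that sum is emitted as an unlisted
#'   `"Other Android"` pseudo-model so platform totals can be set
#'   independently of the per-model table.
#' @param level_mean,level_sd True environmental level process: Gaussian
#'   in dB(C), clipped to `[30, 100]` (defaults 65 and 12, consistent
#'   with observed platform ranges).
#' @param loudness_mean,loudness_sd Per-user mean symptom loudness
#'   process on `[0, 1]` (defaults 0.3 and 0.15).
#' @param loudness_entry_sd Within-user per-entry loudness fluctuation
#'   (default 0.1).
#' @param sigma_db,startup_artifact,clip_max Device noise model passed to
#'   the series simulator (see [simulate_series()]).
#' @param seed Mandatory integer seed.
#' @return A list of class `"database_spec"`.
#' @examples
#' spec <- database_spec(
#'   models = tibble::tibble(model_name = c("Galaxy S7", "Moto G"),
#'                           n_users = c(3, 2),
#'                           n_measurements = c(40, 25)),
#'   n_ios = 30, seed = 42)
#' @export
database_spec <- function(models, n_ios = 0L, n_unknown = 0L,
                          n_android = NULL, level_mean = 65, level_sd = 12,
                          loudness_mean = 0.3, loudness_sd = 0.15,
                          loudness_entry_sd = 0.1, sigma_db = 0.5,
                          startup_artifact = TRUE, clip_max = 32767,
                          seed) {
  if (missing(seed) || is.null(seed)) {
    stop("database_spec requires an explicit seed", call. = FALSE)
  }
  models <- tibble::as_tibble(models)
  stopifnot(all(c("model_name", "n_users", "n_measurements") %in%
                  names(models)))
  if (any(models$n_users < 0) || any(models$n_measurements < 0) ||
      n_ios < 0 || n_unknown < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  bad <- models$n_users > models$n_measurements |
    (models$n_users == 0 & models$n_measurements > 0)
  if (any(bad)) {
    stop("more users than measurements for model(s): ",
         paste(models$model_name[bad], collapse = ", "), call. = FALSE)
  }
  listed <- sum(models$n_measurements)
  if (is.null(n_android)) n_android <- listed
  if (n_android < listed) {
    stop("n_android is smaller than the sum of per-model measurements",
         call. = FALSE)
  }
  structure(
    list(models = models, n_ios = as.integer(n_ios),
         n_unknown = as.integer(n_unknown),
         n_android = as.integer(n_android),
         level_mean = level_mean, level_sd = level_sd,
         loudness_mean = loudness_mean, loudness_sd = loudness_sd,
         loudness_entry_sd = loudness_entry_sd, sigma_db = sigma_db,
         startup_artifact = startup_artifact, clip_max = clip_max,
         seed = as.integer(seed)),
    class = "database_spec"
  )
}

# Deterministic near-equal split of n measurements over m users.
split_over_users <- function(n, m) {
  if (m == 0) return(integer(0))
  base <- n %/% m
  counts <- rep(base, m)
  extra <- n - base * m
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate a synthetic crowdsensed sound-entry database
#'
#' Builds an entry table with the exact per-model user and measurement
#' counts of the spec. Android stored amplitudes are produced by the
#' LEGACY pathway — the arithmetic mean of a full simulated 30-sample
#' series, startup artifacts included — so the synthetic database carries
#' the same averaging bias as the real one. Models present in the
#' registry use their calibration curve; unlisted models get a synthetic
#' curve with the common ~21 dB/decade slope and a seeded device offset.
#' iOS and unknown-platform entries carry no amplitude. Deterministic
#' under the spec's seed.
#'
#' @param spec A [database_spec()].
#' @param registry Registry supplying calibration curves for known models.
#' @param keep_truth Also emit the latent `true_level_db` and the
#'   corrected-average `correct_db` per android entry (default `FALSE`),
#'   for studying the legacy bias against ground truth.
#' @return A tibble of sound entries: `entry_id`, `user_id`, `device_id`,
#'   `platform`, `timestamp`, `stored_amplitude`, `tinnitus_loudness`
#'   (+ truth columns if requested).
#' @examples
#' db <- generate_synthetic_database(database_spec(
#'   models = tibble::tibble(model_name = "Galaxy S7",
#'                           n_users = 2, n_measurements = 10),
#'   seed = 7))
#' @export
generate_synthetic_database <- function(spec,
                                        registry = default_registry(),
                                        keep_truth = FALSE) {
  stopifnot(inherits(spec, "database_spec"))
  withr::with_seed(spec$seed, {
    models <- spec$models
    extra <- spec$n_android - sum(models$n_measurements)
    if (extra > 0) {
      models <- dplyr::bind_rows(models, tibble::tibble(
        model_name = "Other Android",
        n_users = max(1L, as.integer(round(extra / 50))),
        n_measurements = extra
      ))
    }
    android <- purrr::pmap_dfr(
      models,
      function(model_name, n_users, n_measurements) {
        if (n_measurements == 0) return(NULL)
        res <- resolve_device(model_name, registry)
        device_id <- if (res$model_name == "unknown") model_name else
          res$canonical_id
        cal <- if (res$calibrated) {
          device_calibration(res$model_name, res$slope, res$intercept)
        } else {
          # unlisted model: common slope, device-specific offset in 0-15 dB
          device_calibration(model_name, 21, stats::runif(1, 0, 15),
                             source = "synthetic")
        }
        per_user <- split_over_users(n_measurements, n_users)
        user_id <- rep(sprintf("%s_u%03d", gsub("[^A-Za-z0-9]", "",
                                                model_name),
                               seq_len(n_users)), per_user)
        truth <- pmin(pmax(stats::rnorm(n_measurements, spec$level_mean,
                                        spec$level_sd), 30), 100)
        amps <- simulate_amplitude_matrix(
          truth, cal, spec$sigma_db, spec$startup_artifact, spec$clip_max
        )
        stored <- colMeans(amps)
        out <- tibble::tibble(
          user_id = user_id, device_id = device_id, platform = "android",
          stored_amplitude = stored
        )
        if (keep_truth) {
          retained <- amps[-(1:2), , drop = FALSE]
          retained_db <- matrix(
            amplitude_to_db(pmax(retained, 1), cal), nrow(retained)
          )
          out$true_level_db <- truth
          out$correct_db <- 10 * log10(colMeans(10^(retained_db / 10)))
        }
        out
      }
    )
    n_ios_users <- max(1L, as.integer(round(spec$n_ios / 60)))
    ios <- if (spec$n_ios > 0) tibble::tibble(
      user_id = rep(sprintf("ios_u%04d", seq_len(n_ios_users)),
                    split_over_users(spec$n_ios, n_ios_users)),
      device_id = NA_character_, platform = "ios",
      stored_amplitude = NA_real_
    ) else NULL
    unknown <- if (spec$n_unknown > 0) tibble::tibble(
      user_id = sprintf("anon_u%04d", seq_len(spec$n_unknown)),
      device_id = NA_character_, platform = "unknown",
      stored_amplitude = NA_real_
    ) else NULL
    db <- dplyr::bind_rows(android, ios, unknown)
    if (nrow(db) == 0) {
      return(tibble::tibble(entry_id = character(), user_id = character(),
                            device_id = character(), platform = character(),
                            timestamp = character(),
                            stored_amplitude = numeric(),
                            tinnitus_loudness = numeric()))
    }
    # per-user mean loudness, fluctuating per entry; absent where no
    # symptom report accompanies the entry (unknown platform)
    users <- unique(db$user_id)
    user_mu <- clip01(stats::rnorm(length(users), spec$loudness_mean,
                                   spec$loudness_sd))
    names(user_mu) <- users
    db$tinnitus_loudness <- clip01(
      stats::rnorm(nrow(db), user_mu[db$user_id], spec$loudness_entry_sd)
    )
    db$tinnitus_loudness[db$platform == "unknown"] <- NA_real_
    db$entry_id <- sprintf("e%06d", seq_len(nrow(db)))
    db$timestamp <- format(
      as.POSIXct("2020-01-01 00:00:00", tz = "UTC") +
        3600 * seq_len(nrow(db)),
      "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"
    )
    dplyr::select(db, entry_id, user_id, device_id, platform, timestamp,
                  stored_amplitude, tinnitus_loudness,
                  dplyr::any_of(c("true_level_db", "correct_db")))
  })
}
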