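test_that("simulated series follow the noise and artifact contract", {
  s7 <- s7_cal()
  clean <- simulate_series(50, s7, sigma_db = 0, startup_artifact = FALSE,
                           seed = 1)
  expect_length(clean$samples, 30)
  expect_true(all(clean$samples == 234))  # round(233.82)
  art <- simulate_series(50, s7, sigma_db = 0, startup_artifact = TRUE,
                         seed = 2)
  expect_equal(art$samples[1], 0)
  expect_lt(art$samples[2], art$samples[3])
  expect_true(all(art$samples[3:30] == art$samples[3]))
  # determinism and non-interference with the session RNG
  a <- simulate_series(65, s7, seed = 42)
  b <- simulate_series(65, s7, seed = 42)
  expect_identical(a$samples, b$samples)
  expect_false(identical(simulate_series(65, s7, seed = 43)$samples,
                         a$samples))
  # clipping to the recorder ceiling
  loud <- simulate_series(130, s7, sigma_db = 0, seed = 3)
  expect_true(all(loud$samples <= 32767))
})

test_that("noiseless sessions sit on the curve and refit exactly", {
  s7 <- s7_cal()
  sess <- generate_calibration_session(s7, sigma_db = 0, seed = 1)
  expect_equal(nrow(sess), 7)
  expect_equal(sess$reference_db, seq(50, 80, by = 5))
  expect_equal(sess$amplitude, db_to_amplitude(sess$reference_db, s7),
               tolerance = 1e-9)
  fit <- fit_log_calibration(sess)
  expect_equal(fit$calibration$slope, s7$slope, tolerance = 1e-6)
  expect_equal(fit$calibration$intercept, s7$intercept, tolerance = 1e-6)
  expect_equal(fit$calibration$r_squared, 1, tolerance = 1e-6)
})

test_that("noisy seeded sessions refit close to the generating device", {
  s7 <- s7_cal()
  sess <- generate_calibration_session(s7, sigma_db = 0.5, seed = 42)
  fit <- fit_log_calibration(sess)
  expect_equal(fit$calibration$slope, s7$slope, tolerance = 1.5)
  expect_equal(fit$calibration$intercept, s7$intercept, tolerance = 3)
  # agrees with the independent closed-form fit on the same points
  oracle <- ls_oracle(sess$amplitude, sess$reference_db)
  expect_equal(fit$calibration$slope, oracle$slope, tolerance = 1e-8)
})

test_that("all packaged profiles are recoverable end-to-end under noise", {
  reg <- table5_profiles()
  for (i in seq_len(nrow(reg))) {
    truth <- device_calibration(reg$model_name[i], reg$slope[i],
                                reg$intercept[i])
    sess <- generate_calibration_session(truth, sigma_db = 0.5,
                                         seed = 1000 + i)
    fit <- fit_log_calibration(sess, model_name = reg$model_name[i])
    expect_equal(fit$calibration$slope, reg$slope[i], tolerance = 2)
    expect_equal(fit$calibration$intercept, reg$intercept[i], tolerance = 4)
  }
})

test_that("synthetic databases honour their spec exactly", {
  spec <- database_spec(
    models = tibble::tibble(model_name = c("Galaxy S7", "Moto G"),
                            n_users = c(2, 1), n_measurements = c(10, 5)),
    n_ios = 8, n_unknown = 2, seed = 7)
  db <- generate_synthetic_database(spec)
  expect_equal(nrow(db), 25)
  s7 <- dplyr::filter(db, device_id == "SM-G930F")
  expect_equal(nrow(s7), 10)
  expect_equal(dplyr::n_distinct(s7$user_id), 2)
  expect_equal(sum(db$platform == "ios"), 8)
  expect_equal(sum(db$platform == "unknown"), 2)
  # amplitudes present iff android
  expect_true(all(is.na(db$stored_amplitude[db$platform != "android"])))
  expect_true(all(!is.na(db$stored_amplitude[db$platform == "android"])))
  # loudness fluctuates within users (never constant by construction)
  by_user <- db |>
    dplyr::filter(platform == "android") |>
    dplyr::group_by(user_id) |>
    dplyr::summarise(k = dplyr::n_distinct(tinnitus_loudness))
  expect_true(all(by_user$k > 1))
  # determinism: same spec + seed -> identical table
  expect_identical(generate_synthetic_database(spec), db)
  # inconsistent specs are refused
  expect_error(database_spec(
    models = tibble::tibble(model_name = "m", n_users = 5,
                            n_measurements = 2), seed = 1),
    "more users")
  expect_error(database_spec(
    models = tibble::tibble(model_name = "m", n_users = 1,
                            n_measurements = 2)),
    "seed")
})

test_that("composition of a spec-built database round-trips the spec", {
  spec <- database_spec(
    models = tibble::tibble(
      model_name = c("Galaxy S7", "Moto G", "Galaxy A3"),
      n_users = c(4, 2, 3),
      n_measurements = c(60, 35, 44)),
    n_ios = 50, n_unknown = 5, seed = 31)
  comp <- dataset_composition(generate_synthetic_database(spec))
  expect_equal(comp$platforms$n[comp$platforms$platform == "android"], 139L)
  expect_equal(comp$platforms$n[comp$platforms$platform == "ios"], 50L)
  got <- dplyr::arrange(comp$models, model_name)
  want <- dplyr::arrange(spec$models, model_name)
  expect_equal(got$model_name, want$model_name)
  expect_equal(got$n_users, want$n_users)
  expect_equal(got$n_measurements, want$n_measurements)
})

test_that("stored legacy values understate the energetic truth", {
  mk <- function(sigma, seed) {
    spec <- database_spec(
      models = tibble::tibble(model_name = "Galaxy S7", n_users = 4,
                              n_measurements = 300),
      sigma_db = sigma, seed = seed)
    db <- generate_synthetic_database(spec, keep_truth = TRUE)
    legacy_db <- amplitude_to_db(pmax(db$stored_amplitude, 1), s7_cal())
    mean(db$correct_db - legacy_db)
  }
  bias_small <- mk(0.2, 61)
  bias_large <- mk(2.0, 62)
  expect_gt(bias_small, 0)
  # the understatement grows with the within-series level spread
  expect_gt(bias_large, bias_small)
})
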