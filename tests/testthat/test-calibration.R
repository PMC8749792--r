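test_that("packaged registry reproduces the published device profiles", {
  reg <- default_registry()
  expected <- table5_profiles()
  for (i in seq_len(nrow(expected))) {
    cal <- registry_calibration(expected$model_name[i], reg)
    # x = 1 returns the printed intercept exactly
    expect_identical(amplitude_to_db(1, cal), expected$intercept[i])
    expect_identical(cal$slope, expected$slope[i])
    expect_identical(cal$r_squared, expected$r_squared[i])
  }
  # a decade of amplitude adds one slope: x = 10 -> a + b
  expect_equal(amplitude_to_db(10, registry_calibration("Galaxy S7", reg)),
               21.886, tolerance = 1e-9)
  expect_equal(amplitude_to_db(10, registry_calibration("Moto G", reg)),
               35.474, tolerance = 1e-9)
})

test_that("amplitude/dB conversion inverts exactly and rejects bad input", {
  s7 <- s7_cal()
  expect_equal(db_to_amplitude(1.3481, s7), 1, tolerance = 1e-12)
  expect_equal(db_to_amplitude(50, s7), 233.82119102, tolerance = 1e-8)
  lv <- seq(50, 80, by = 0.5)
  expect_equal(amplitude_to_db(db_to_amplitude(lv, s7), s7), lv,
               tolerance = 1e-9)
  # strictly increasing in amplitude for positive slope
  x <- sort(10^runif(20, 0, 4.5))
  expect_true(all(diff(amplitude_to_db(x, s7)) > 0))
  expect_error(amplitude_to_db(0, s7), "positive")
  expect_error(amplitude_to_db(-3, s7), "positive")
  expect_error(device_calibration("bad", -1, 0), "slope")
})

test_that("noiseless sessions recover their generating curve exactly", {
  withr::with_seed(303, {
    for (i in 1:10) {
      a <- runif(1, 10, 30)
      b <- runif(1, -5, 20)
      truth <- device_calibration("sim", a, b)
      pts <- tibble::tibble(
        reference_db = seq(50, 80, by = 5),
        amplitude = db_to_amplitude(reference_db, truth)
      )
      fit <- fit_log_calibration(pts, model_name = "sim")
      expect_equal(fit$calibration$slope, a, tolerance = 1e-6)
      expect_equal(fit$calibration$intercept, b, tolerance = 1e-6)
      expect_equal(fit$calibration$r_squared, 1, tolerance = 1e-6)
    }
  })
  # two points define the line exactly
  fit2 <- fit_log_calibration(
    tibble::tibble(reference_db = c(50, 70), amplitude = c(100, 1000))
  )
  expect_equal(fit2$calibration$slope, 20)
  expect_equal(fit2$calibration$intercept, 10)
  expect_equal(fit2$calibration$r_squared, 1)
})

test_that("degenerate calibration designs are refused", {
  expect_error(
    fit_log_calibration(tibble::tibble(reference_db = 50, amplitude = 100)),
    "two points")
  expect_error(
    fit_log_calibration(tibble::tibble(reference_db = c(50, 60),
                                       amplitude = c(100, 100))),
    "distinct")
  expect_error(
    fit_log_calibration(tibble::tibble(reference_db = c(50, 60),
                                       amplitude = c(0, 100))),
    "positive")
})

test_that("fit agrees with an independent closed-form least squares", {
  withr::with_seed(404, {
    truth <- s7_cal()
    pts <- tibble::tibble(
      reference_db = seq(50, 80, by = 5) + rnorm(7, 0, 0.5),
      amplitude = db_to_amplitude(seq(50, 80, by = 5), truth)
    )
    fit <- fit_log_calibration(pts)
    oracle <- ls_oracle(pts$amplitude, pts$reference_db)
    expect_equal(fit$calibration$slope, oracle$slope, tolerance = 1e-8)
    expect_equal(fit$calibration$intercept, oracle$intercept,
                 tolerance = 1e-8)
    expect_equal(fit$calibration$r_squared, oracle$r_squared,
                 tolerance = 1e-8)
    expect_equal(fit$calibration$slope, truth$slope, tolerance = 1.5)
    expect_equal(fit$calibration$intercept, truth$intercept, tolerance = 3)
    expect_lt(fit$calibration$r_squared, 1)
  })
})

test_that("slope is invariant under a constant shift of reference levels", {
  pts <- tibble::tibble(
    reference_db = seq(50, 80, by = 5),
    amplitude = db_to_amplitude(reference_db, s7_cal()) *
      exp(c(0.02, -0.01, 0.03, 0, -0.02, 0.01, 0))
  )
  f1 <- fit_log_calibration(pts)
  f2 <- fit_log_calibration(dplyr::mutate(pts,
                                          reference_db = reference_db + 7))
  expect_equal(f2$calibration$slope, f1$calibration$slope, tolerance = 1e-9)
  expect_equal(f2$calibration$intercept, f1$calibration$intercept + 7,
               tolerance = 1e-9)
})

test_that("single-point offset calibration solves for the intercept", {
  s7 <- s7_cal()
  cal <- offset_calibration(50, db_to_amplitude(50, s7),
                            reference_slope = s7$slope)
  expect_equal(cal$intercept, 1.3481, tolerance = 1e-9)
  expect_equal(offset_calibration(65, 1000, 21)$intercept, 2)
  expect_true(is.na(offset_calibration(65, 1000, 21)$r_squared))
  # noiseless one-point recovery of a known device
  truth <- device_calibration("sim", 22.1, 6.5)
  got <- offset_calibration(72, db_to_amplitude(72, truth), 22.1)
  expect_equal(got$intercept, 6.5, tolerance = 1e-9)
  expect_error(offset_calibration(50, 0, 21), "positive")
})

test_that("tidy and glance expose fit results broom-style", {
  fit <- fit_log_calibration(
    generate_calibration_session(s7_cal(), sigma_db = 0.3, seed = 5),
    model_name = "Galaxy S7")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 7L)
  expect_true(gl$r.squared > 0.99 && gl$r.squared <= 1)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("device IDs resolve through exact match, aliases, and unknowns", {
  reg <- default_registry()
  hit <- resolve_device("SM-G930F", reg)
  expect_equal(hit$model_name, "Galaxy S7")
  expect_equal(hit$slope, 20.5379)
  alias <- resolve_device("XT1028", reg)
  expect_equal(alias$model_name, "Moto G")
  expect_equal(alias$canonical_id, "XT1032")
  expect_equal(alias$slope, 21.216)
  # the paper-style group spans all three Moto G IDs
  grp <- resolve_device(c("Moto G", "XT1028", "XT1032"), reg)
  expect_equal(unique(grp$model_name), "Moto G")
  unk <- resolve_device("NONEXISTENT-ID", reg)
  expect_equal(unk$model_name, "unknown")
  expect_false(unk$calibrated)
  expect_true(is.na(unk$slope))
  expect_error(registry_calibration("NONEXISTENT-ID", reg),
               "no calibration")
})

test_that("registry JSON round-trips through read_registry", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[
    {"device_id":"DEV-1","model_name":"Demo","aliases":["DEV-1b"],
     "slope":21.0,"intercept":2.0,"r_squared":0.99,"source":"test"},
    {"device_id":"DEV-2","model_name":"Bare","aliases":[],
     "slope":null,"intercept":null,"r_squared":null,"source":"test"}
  ]', path)
  reg <- read_registry(path)
  expect_equal(nrow(reg), 3)  # alias expanded
  expect_equal(resolve_device("DEV-1b", reg)$model_name, "Demo")
  expect_false(resolve_device("DEV-2", reg)$calibrated)
  # duplicate IDs are rejected
  writeLines('[
    {"device_id":"X","model_name":"A","aliases":[],"slope":null,
     "intercept":null,"r_squared":null,"source":"t"},
    {"device_id":"X","model_name":"B","aliases":[],"slope":null,
     "intercept":null,"r_squared":null,"source":"t"}
  ]', path)
  expect_error(read_registry(path), "duplicate")
})
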