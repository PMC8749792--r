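Package: crowdnoise
Title: Calibration and Harmonization of Crowdsensed Smartphone Sound Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for making uncalibrated smartphone sound-level amplitudes
    collected by mobile-crowdsensing mHealth platforms comparable and
    interpretable. Provides device-specific logarithmic calibration curves
    (fit, store, apply, invert), energetic (equivalent-continuous) averaging
    of sound levels, auditing of the legacy arithmetic-averaging error
    including worst-case simulation, bulk transformation of stored amplitude
    values into dB(C), dataset composition and per-user plausibility reports,
    and seeded generators that emulate both the calibration experiment and a
    crowdsensed sound-entry database.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
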