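# crowdnoise

Calibration and harmonization of crowdsensed smartphone sound levels.

Mobile-crowdsensing mHealth platforms capture an environmental sound
measurement while users fill in symptom questionnaires — but what lands in
the database is the raw recorder amplitude: a unitless, device-dependent
number that was arithmetically averaged over the 15 s measurement window.
Such values are neither comparable across devices nor interpretable as
sound levels. `crowdnoise` is for researchers who have inherited such a
database (or are building a sensing pipeline and want to avoid inheriting
one): it turns stored amplitudes into (partially) comparable dB(C) values
and quantifies exactly how much the legacy pipeline distorted them.

## The model

Each device model gets a logarithmic calibration curve fitted from bench
measurements against a reference sound level meter at 1000 Hz (where A- and
C-weighting apply zero offset, so dB SPL = dB(A) = dB(C)):

```
y = a · log10(x) + b        y: level [dB(C)], x: recorder amplitude
```

with slope `a` (dB per decade of amplitude) and intercept `b` fitted by
ordinary least squares on the dB response. Five fully calibrated profiles
ship in the packaged registry, e.g. the Galaxy S7's
`y = 20.5379·log10(x) + 1.3481` (R² = 0.9995).

Averaging is done energetically, never arithmetically: for equal-duration
samples the equivalent continuous level is

```
Leq = 10 · log10( (1/N) · Σ 10^(Li/10) )
```

Because `10^(L/10)` is convex, the legacy arithmetic average of amplitudes
never exceeds the energetic truth — the stored database systematically
understates loudness, and `worst_case_error()` shows by how much.

## Worked example

```r
library(crowdnoise)
library(dplyr)

s7 <- registry_calibration("Galaxy S7")
s7
#> <device_calibration> Galaxy S7
#>   y = 20.5379 * log10(x) + 1.3481  [dB(C)]
#>   R^2 = 0.9995

# one simulated 15 s measurement of a steady 65 dB(C) tone
series <- simulate_series(true_level = 65, s7, sigma_db = 0.5, seed = 7)
head(series$samples, 5)
#> [1]    0  232 1429 1175 1209

detect_startup_artifact(series)[, 1:3]
#>   first_sample_zero second_sample_low any_artifact
#> 1 TRUE              TRUE              TRUE

amplitude_to_db(legacy_average(series), s7)  # what the app stored
#> 64.7 dB(C)  (arithmetic mean of all 30 samples, artifacts included)
corrected_average(series, s7)                # discard 2, energetic mean
#> 65.3 dB(C)

# the published-style worst-case audit across all calibrated models
error_table() |>
  select(model_name, legacy_db_disp, correct_db_disp, difference_disp)
#>   model_name     legacy_db_disp correct_db_disp difference_disp
#> 1 Galaxy S7                55.9            65.4             9.5
#> 2 Galaxy A3                55.8            65.4             9.6
#> 3 Moto G                   55.6            65.4             9.8
#> 4 Moto G 5S Plus           55.5            65.4             9.9
#> 5 Pixel 2                  54.7            65.4            10.7
```

A worst-case measurement — 29 quiet samples at 50 dB(C) plus one loud burst
at 80 dB(C) — is stored by the legacy pipeline as 55.9 dB(C) on a Galaxy S7
although its equivalent continuous level is 65.4 dB(C): the stored value
understates the actual loudness by about 9.5 dB, roughly a factor of two in
perceived loudness.

Bulk transformation of a (here: synthetic) entry database:

```r
db <- generate_synthetic_database(database_spec(
  models = tibble::tibble(model_name = c("Galaxy S7", "Moto G"),
                          n_users = c(4, 2), n_measurements = c(120, 60)),
  n_ios = 80, n_unknown = 3, seed = 42))

tr <- transform_entries(db)
count(tr, status)
#>   status          n
#> 1 converted     180
#> 2 non_android    83

summarize_levels(tr)
#>   model_name     n min_db max_db avg_db energetic_avg_db
#> 1 Galaxy S7    120   29.6   93.7   64.9             78.3
#> 2 Moto G        60   35.4   95.6   64.0             80.3
```

Every input entry comes back exactly once with a status (`converted`,
`no_calibration`, `invalid_amplitude`, `non_android`); both the arithmetic
and the energetic mean are reported so the averaging choice stays visible.

See `vignette("calibrating-crowdsensed-sound-levels")` for the full account
of the model, the generators, and the design decisions.

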