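---
title: "Calibrating crowdsensed smartphone sound levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating crowdsensed smartphone sound levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdnoise)
library(dplyr)
```

## The problem

Mobile-crowdsensing mHealth platforms record an environmental sound
measurement while a user fills in a symptom questionnaire: the platform this
package models polls the recorder's maximum absolute amplitude every 500 ms
for 15 s (30 integer samples on a device-dependent 0–32767 scale), averages
them, and stores that single number. Years of such data accumulate before
anyone asks what the numbers mean, at which point three problems surface:

1. **The scale is device-specific.** A raw amplitude of 500 is a different
   loudness on every handset model; raw values are not comparable across
   users.
2. **The stored average is the wrong average.** The deployed app averaged
   the amplitude samples arithmetically. Sound levels are logarithmic:
   equal-duration samples must be averaged energetically
   (the equivalent continuous level,
   $L_{eq} = 10\log_{10}\!\big(\tfrac1N\sum_i 10^{L_i/10}\big)$).
   The arithmetic path systematically understates loudness — by up to
   roughly 9–10 dB in the worst observed measurement shape.
3. **The first second of recording is unreliable.** On several handsets the
   first polled sample is exactly 0 and the second is depressed.

`crowdnoise` implements the retroactive repair: bench-style calibration
curves per device model, the corrected averaging, an audit that quantifies
the legacy error, and bulk transformation of stored values into dB(C).

## The calibration model

For each device model a bench experiment plays a steady 1000 Hz pure tone at
reference levels measured with a class-2 sound level meter, and records the
amplitude the device reports. At 1000 Hz the A- and C-weighting filters
apply zero offset, so dB SPL, dB(A) and dB(C) coincide there; levels are
reported as dB(C) throughout. The amplitude–level relationship is modelled
as

$$ y = a \cdot \log_{10}(x) + b, $$

with $y$ the reference level in dB(C), $x$ the device amplitude, $a$ the
slope in dB per decade of amplitude and $b$ the intercept in dB(C). The
model is fitted by ordinary least squares with the dB level as the response
(`fit_log_calibration()`), and goodness of fit is the coefficient of
determination $R^2 = 1 - SS_{res}/SS_{tot}$. The form mirrors the
definition of sound pressure level, $L_p = 20\log_{10}(p/p_0)$ with
$p_0 = 20\,\mu\mathrm{Pa}$: fitted slopes cluster near 20–24 dB/decade,
i.e. devices process sound nearly identically up to an offset. That
near-common slope is what justifies `offset_calibration()`: an additional
device can be approximately calibrated from a single reference point by
borrowing a known slope and solving only for the intercept.

Five fully calibrated profiles ship in the packaged registry
(`default_registry()`), together with device-ID-to-model mappings for the
most common handsets in the platform database. Alias groups collect
multiple platform IDs under one model (all three "Moto G" IDs share one
curve). Registry matching is case-sensitive exact string comparison,
because device IDs are verbatim platform build constants.

## Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| calibration levels | 50–80 dB(C), 5 dB steps | dB(C) | bench protocol: background noise floor ~46 dB(C) below, hearing safety above |
| `n_samples` | 30 | samples | 15 s at 500 ms per poll |
| `n_discard` | 2 | samples | first two samples unreliable within the first 1000 ms |
| `sigma_db` | 0.5 | dB | per-sample microphone/readout noise in the simulator |
| `clip_max` | 32767 | amplitude | 16-bit recorder ceiling |
| `min_entries` | 500 | entries | per-user inclusion threshold for longitudinal analyses |
| `range_low`, `range_high` | 50, 80 | dB(C) | fitted range; conversions outside are tagged `extrapolated`, not refused |

Amplitudes below 1 cannot be pushed through the logarithmic curve
(`log10(0)` is undefined); they are flagged (`invalid_amplitude`), never
silently dropped or clamped.

## Auditing the legacy error

`legacy_average()` reproduces the deployed app's stored value exactly: the
arithmetic mean of all 30 raw samples, startup artifacts included.
`corrected_average()` is the repaired pipeline: discard two, convert each
retained sample to dB(C), average energetically. Because $10^{L/10}$ is
convex, the legacy value never exceeds the corrected one (equality only for
a constant series) — the stored database systematically understates
loudness.

`worst_case_error()` quantifies the bias at its observed extreme: 29
samples at the quiet end of the calibrated range and one at the loud end.

```{r worst-case}
error_table() |>
  select(model_name, legacy_db_disp, correct_db_disp, difference_disp)
```

The amplitudes in this audit are *reconstructed* by inverting each model's
fitted curve at 50 and 80 dB(C), because the raw bench amplitudes are not
retained as data. For the device whose curve fits its measurements most
tightly the reconstruction reproduces the bench audit to display precision;
for the others it agrees to a few tenths of a dB. Reconstruction uses
continuous amplitudes by default; `round_amplitudes = TRUE` quantises to
integers and moves results by under 0.05 dB. The "correct" column uses
power-form averaging ($10\log_{10}$ of mean $10^{L/10}$), the standard
$L_{eq}$ definition; pressure-RMS averaging would give a value about
0.35 dB lower and is not used.

Two legacy problems are documented but deliberately *not* simulated: the
narrowband voice codec (200–3400 Hz) used for capture, which distorts
energy outside its band, and user interference (covered microphones,
devices placed on tables). Neither is a reproducible computation; both are
caveats that travel with transformed outputs.

## Transforming a stored database

`transform_entries()` converts a whole entry table, keeping every row:
each entry ends as `converted` (with `db_c`), `no_calibration`,
`invalid_amplitude`, or `non_android` (iOS stores a relative dB value on an
unknown scale; it is carried, not converted). `summarize_levels()` reports
per-model minimum, maximum and *both* the arithmetic and the energetic mean
of converted levels — the arithmetic mean of dB values is the conventional
summary but has no clean acoustic meaning, so the choice is kept visible
rather than baked in. `dataset_composition()` and `plausibility_screen()`
reproduce the standard dataset reports: platform shares (percentages
rounded half-up to two decimals), per-model user and measurement counts
with measurements-per-user rounded to the nearest integer, and per-user
eligibility (more than `min_entries` measurements, fluctuating symptom and
amplitude streams).

## What the synthetic data emulate — and what they do not

No real platform database ships with this package. The generators exist so
the full pipeline is testable end to end:

* `simulate_series()` — one measurement by a device with a known curve:
  per-sample Gaussian noise in dB (multiplicative gain error, hence
  log-normal in amplitude — this keeps the regression model
  well-specified), integer quantisation, ceiling clipping, and the
  observed startup artifact (first sample 0, second a uniform fraction in
  $[0,1)$ of the third; the bench observation says only "often too low",
  so a concrete distribution had to be chosen).
* `generate_calibration_session()` — the bench protocol: seven levels,
  50–80 dB(C) in 5 dB steps, one corrected-average-derived amplitude per
  level. Samples stay continuous by default so a noiseless session lies
  exactly on the generating curve and refits recover $(a, b)$ to $10^{-6}$;
  integer quantisation is available where recorder fidelity matters more
  than exact recovery.
* `generate_synthetic_database()` — a platform-scale entry table with exact
  per-model user and measurement counts. Android amplitudes are produced by
  the *legacy* pathway (arithmetic mean of the full simulated series,
  artifacts included) so the synthetic database carries the same bias as
  the real one. True levels are drawn from a Gaussian in dB(C) (mean 65,
  sd 12) clipped to [30, 100], consistent with the observed range of
  transformed platform values; per-user symptom loudness follows a
  Gaussian user mean (0.3, sd 0.15) with per-entry fluctuation (sd 0.1),
  clipped to [0, 1]. All generators are pure functions of (spec, seed).

What passing tests on these data do **not** show: real microphones have
frequency-dependent responses and codec band-limiting; real soundscapes are
not steady tones, so the within-measurement spread is larger and more
skewed than Gaussian dB noise; real users' devices, habits and environments
correlate. Parameter-recovery and bias results here validate the
*arithmetic* of the pipeline, not the field accuracy of any device.

## Numerical choices

* Internal values keep full double precision; `round_db()` (half-up,
  0.1 dB — the meter's resolution) is applied only at presentation.
* $R^2$ is computed directly from residual and total sums of squares, so a
  noiseless (exact) fit returns 1 without the near-singular-summary
  warnings `summary.lm()` emits.
* The worst-case difference is independent of the intercept (it cancels in
  correct − legacy) but grows with the slope and with the quiet/loud gap;
  both facts are asserted in the test suite.
* Degenerate inputs fail loudly: empty series, fewer than two distinct
  amplitudes in a fit, non-positive amplitudes, mixed weighting tags,
  database specs with more users than measurements.

## Design decisions that were genuinely open

* **Legacy mode averages all 30 samples.** Whether the deployed app's
  stored value covered 30 or 28 samples is not fully documented; the
  discard rule is described as an experiment-app correction, so legacy = 30
  is assumed (and both modes are exposed, so the audit can quantify their
  gap on identical input).
* **"Second sample too low" needed a testable rule.** The artifact flag
  fires when the second sample is below half the median of samples 3–30.
  Flag-only: repairs are the discard rule's job.
* **Arithmetic vs energetic summary means.** Database-wide per-model
  summaries emit both, because which one a downstream analysis should use
  depends on whether entries are treated as exposure (energetic) or as
  repeated observations of a covariate (arithmetic).
* **No extrapolation guard.** Conversions outside 50–80 dB(C) are allowed
  but tagged, since stored databases demonstrably contain values on both
  sides of the calibrated range.

## Problem sizes used in the shipped checks

The test suite fits sessions of 7 points, series of 30 samples, synthetic
databases of tens to a few hundred entries for structural checks, and one
full-scale composition check of 76,542 entries; property loops run 10–25
seeded repetitions. The whole suite completes in a few seconds on one CPU.

## Known limitations

Calibration profiles exist for five device models; everything else is
`no_calibration` until someone runs `fit_log_calibration()` or
`offset_calibration()` on new bench data and adds the profile to a registry
JSON. iOS values are carried but never converted. Frequency weighting is
metadata — measurements away from 1000 Hz would need real filter curves.
And all transformed historical values inherit the legacy bias: they are
comparable with each other, usable for relative and correlational analyses,
but are not reference-grade noise dosimetry.
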