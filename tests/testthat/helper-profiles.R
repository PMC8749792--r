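# The five experimentally calibrated device profiles, stated independently
# of the packaged registry file so tests can cross-check it.
table5_profiles <- function() {
  tibble::tribble(
    ~device_id,         ~model_name,      ~slope,   ~intercept, ~r_squared,
    "SM-G930F",         "Galaxy S7",      20.5379,  1.3481,     0.9995,
    "SM-A310F",         "Galaxy A3",      20.7228,  1.2215,     0.9997,
    "XT1032",           "Moto G",         21.216,   14.258,     0.9994,
    "Moto G (5S) Plus", "Moto G 5S Plus", 21.341,   10.166,     0.9998,
    "Pixel 2",          "Pixel 2",        23.8364,  -2.7633,    0.9925
  )
}

s7_cal <- function() device_calibration("Galaxy S7", 20.5379, 1.3481, 0.9995)

# Independent closed-form least squares of y on log10(x): the oracle the
# lm-backed fit is checked against.
ls_oracle <- function(amplitude, level) {
  lx <- log10(amplitude)
  slope <- sum((lx - mean(lx)) * (level - mean(level))) /
    sum((lx - mean(lx))^2)
  intercept <- mean(level) - slope * mean(lx)
  fitted <- slope * lx + intercept
  r2 <- 1 - sum((level - fitted)^2) / sum((level - mean(level))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Small entry-table builder for transform tests.
make_entries <- function(device_id, platform = "android", amplitude = 100,
                         user_id = "u1", n = length(device_id)) {
  tibble::tibble(
    entry_id = sprintf("e%04d", seq_len(n)),
    user_id = rep_len(user_id, n),
    device_id = rep_len(device_id, n),
    platform = rep_len(platform, n),
    timestamp = "2020-01-01T00:00:00Z",
    stored_amplitude = rep_len(amplitude, n)
  )
}
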