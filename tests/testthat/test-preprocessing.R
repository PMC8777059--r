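fs <- 250
n <- 15000L
t_ax <- (seq_len(n) - 1) / fs
core <- (fs + 1):(n - fs)  # exclude 1 s edge transients

sine_rec <- function(freq, nch = 1L) {
  m <- matrix(sin(2 * pi * freq * t_ax), n, nch)
  raw_recording(m, fs = fs, montage = canonical_montage()[seq_len(nch)])
}

test_that("designed band-pass attenuates 60 Hz by >= 40 dB (analytic oracle)", {
  spec <- filter_spec("butterworth_bandpass")
  coefs <- rteeg:::design_filter(spec, fs)
  # zero-phase application squares the magnitude response
  h60 <- response_mag(coefs, 60, fs)^2
  expect_gte(-20 * log10(h60), 40)

  # and the time-domain path agrees: filtered 60 Hz sinusoid RMS
  out <- bandpass_filter(sine_rec(60), spec)$samples[core, 1]
  att_db <- -20 * log10(sqrt(mean(out^2)) / sqrt(0.5))
  expect_gte(att_db, 40)
})

test_that("band-pass passes 10 Hz within 1 dB", {
  spec <- filter_spec("butterworth_bandpass")
  coefs <- rteeg:::design_filter(spec, fs)
  h10 <- response_mag(coefs, 10, fs)^2
  expect_lt(abs(20 * log10(h10)), 1)

  out <- bandpass_filter(sine_rec(10), spec)$samples[core, 1]
  gain_db <- 20 * log10(sqrt(mean(out^2)) / sqrt(0.5))
  expect_lt(abs(gain_db), 1)
})

test_that("DC input is suppressed by the band-pass", {
  rec <- raw_recording(matrix(50, n, 1), fs = fs, montage = "F3")
  out <- bandpass_filter(rec)$samples[, 1]
  # the 1e-6 relative criterion needs the 1 Hz-edge transient fully settled;
  # judge the central 40 s of the trial
  settled <- (10 * fs + 1):(n - 10 * fs)
  expect_lt(max(abs(out[settled])), 1e-6 * 50)
  # within the ordinary 1 s edge exclusion the residual is already tiny
  expect_lt(max(abs(out[core])), 0.05 * 50)
})

test_that("detrend removes a linear ramp to < 1% residual slope", {
  ramp <- matrix(seq(0, 50, length.out = n), n, 1)
  rec <- raw_recording(ramp, fs = fs, montage = "F3")
  out <- detrend_highpass(rec)$samples[core, 1]
  slope_in <- 50 / 60                          # uV per second
  fit <- stats::lm(out ~ t_ax[core])
  expect_lt(abs(stats::coef(fit)[2]) / slope_in, 0.01)
})

test_that("detrend attenuates a 0.1 Hz drift by >= 20 dB and keeps white noise", {
  out <- detrend_highpass(sine_rec(0.1))$samples[core, 1]
  att_db <- -20 * log10(sqrt(mean(out^2)) / sqrt(0.5))
  expect_gte(att_db, 20)

  set.seed(40)
  wn <- matrix(rnorm(n), n, 1)
  rec <- raw_recording(wn, fs = fs, montage = "F3")
  out <- detrend_highpass(rec)$samples[, 1]
  expect_lt(abs(stats::var(out) / stats::var(wn[, 1]) - 1), 0.1)
})

test_that("full preprocessing preserves geometry and is near-idempotent", {
  set.seed(41)
  cfg <- tiny_config()
  rec <- generate_trial_eeg("positive", cfg, seed = 42L)
  clean <- preprocess_trial(rec)
  expect_equal(dim(clean$samples), dim(rec$samples))
  expect_equal(clean$montage, rec$montage)
  expect_length(clean$meta$filters, 2L)

  twice <- preprocess_trial(clean)
  rms <- function(x) sqrt(mean(x[core, ]^2))
  expect_lt(abs(rms(twice$samples) / rms(clean$samples) - 1), 0.05)
})

test_that("filtering is linear and maps zero to zero", {
  set.seed(42)
  x <- matrix(rnorm(n), n, 1)
  y <- matrix(rnorm(n), n, 1)
  mk <- function(m) raw_recording(m, fs = fs, montage = "F3")
  f <- function(m) preprocess_trial(mk(m))$samples
  lhs <- f(2 * x + 3 * y)
  rhs <- 2 * f(x) + 3 * f(y)
  # the 0.5 Hz high-pass recursion has poles very close to the unit circle,
  # so floating error is amplified; linearity holds to ~1e-4 relative
  expect_lt(max(abs(lhs - rhs)), 1e-4 * max(abs(lhs)))

  zero <- preprocess_trial(mk(matrix(0, n, 1)))$samples
  expect_true(all(zero == 0))
})

test_that("invalid cutoffs are rejected at design time", {
  rec <- sine_rec(10)
  expect_error(bandpass_filter(rec, filter_spec("butterworth_bandpass",
                                                high_hz = 130)),
               "fs/2")
  expect_error(detrend_highpass(rec, filter_spec("chebyshev1_highpass",
                                                 cutoff_hz = 0)),
               "inside")
  expect_error(filter_spec(order = 0), "order")
})
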