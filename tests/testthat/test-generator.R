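test_that("cohort has n_subjects x n_trials sessions with full-length trials", {
  cfg <- tiny_config()
  coh <- generate_cohort(cfg)
  expect_s3_class(coh, "synthetic_cohort")
  expect_length(coh, 6L)
  for (s in coh$sessions) {
    expect_equal(nrow(s$recording$samples), 15000L)
    expect_equal(s$recording$montage, canonical_montage())
    expect_true(s$true_label %in% c("positive", "negative", "excluded"))
  }
})

test_that("default configuration yields a 396-session cohort", {
  coh <- generate_cohort(generator_config(seed = 2L), signals = FALSE)
  expect_length(coh, 11L * 36L)
})

test_that("generation is deterministic given the seed", {
  c1 <- generate_cohort(tiny_config(seed = 7L))
  c2 <- generate_cohort(tiny_config(seed = 7L))
  expect_identical(c1, c2)
  c3 <- generate_cohort(tiny_config(seed = 8L))
  expect_false(identical(c1$sessions[[1]]$recording$samples,
                         c3$sessions[[1]]$recording$samples))
})

test_that("stratified generation hits exact class counts and labeling recovers them", {
  cfg <- generator_config(stratify = c(positive = 126L, negative = 69L,
                                       excluded = 201L), seed = 4L)
  coh <- generate_cohort(cfg, signals = FALSE)
  truth <- vapply(coh$sessions, `[[`, character(1), "true_label")
  expect_equal(sum(truth == "positive"), 126L)
  expect_equal(sum(truth == "negative"), 69L)
  # labeling the stored ratings must recover the generator's composition
  s <- summarize_labels(cohort_ratings(coh))
  expect_equal(unname(s$ps), c(126L, 69L, 201L))
})

test_that("label mix calibrates to its target proportions at n = 396", {
  cfg <- generator_config(seed = 10L)
  coh <- generate_cohort(cfg, signals = FALSE)
  truth <- vapply(coh$sessions, `[[`, character(1), "true_label")
  p_hat <- mean(truth == "positive")
  p <- cfg$label_mix[["positive"]]
  # 3 binomial SDs at n = 396
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / 396))
})

test_that("generated ratings round-trip through the PS rule", {
  set.seed(21)
  for (lab in c("positive", "negative", "excluded")) {
    for (i in 1:200) {
      expect_equal(label_ps(generate_ratings(lab)), lab)
    }
  }
})

test_that("positive ratings have pleasure >= 1 and stress = 1", {
  set.seed(22)
  for (i in 1:100) {
    r <- generate_ratings("positive")
    expect_gte(r$pleasure, 1L)
    expect_equal(r$stress, 1L)
  }
})

test_that("alpha asymmetry matches the configured effect size (Welch oracle)", {
  cfg <- tiny_config(effect_size = 1, line_noise_amp = 0, drift_amp = 0)
  n_rep <- 40L
  set.seed(31)
  lr_diff <- function(label) {
    vapply(seq_len(n_rep), function(i) {
      rec <- generate_trial_eeg(label, cfg)
      lp <- welch_band_power(rec$samples[, "F7"], cfg$fs, 8, 13) +
        welch_band_power(rec$samples[, "T7"], cfg$fs, 8, 13)
      rp <- welch_band_power(rec$samples[, "F8"], cfg$fs, 8, 13) +
        welch_band_power(rec$samples[, "T8"], cfg$fs, 8, 13)
      log(lp / rp)
    }, numeric(1))
  }
  d <- mean(lr_diff("positive")) - mean(lr_diff("negative"))
  # the class difference of the log-ratio is the effect size, within 20%
  expect_gt(d, 0.8)
  expect_lt(d, 1.2)
})

test_that("zero effect size yields class-indistinguishable alpha asymmetry", {
  cfg <- tiny_config(effect_size = 0, line_noise_amp = 0, drift_amp = 0)
  set.seed(32)
  asym <- function(label, n_rep = 25L) {
    vapply(seq_len(n_rep), function(i) {
      rec <- generate_trial_eeg(label, cfg)
      log(welch_band_power(rec$samples[, "F7"], cfg$fs, 8, 13) /
            welch_band_power(rec$samples[, "F8"], cfg$fs, 8, 13))
    }, numeric(1))
  }
  tt <- stats::t.test(asym("positive"), asym("negative"))
  expect_gt(tt$p.value, 0.01)
})

test_that("band-power targets are recovered by the periodogram oracle", {
  cfg <- tiny_config(effect_size = 0, line_noise_amp = 0, drift_amp = 0)
  set.seed(33)
  # average across several trials; F3 carries no lateral effect
  alpha <- theta <- beta <- 0
  n_rep <- 10L
  for (i in seq_len(n_rep)) {
    x <- generate_trial_eeg("positive", cfg)$samples[, "F3"]
    # periodogram normalization: total power over all bins = variance * win
    win <- 2 * cfg$fs
    tot <- welch_band_power(x, cfg$fs, 0, cfg$fs / 2)
    scale <- stats::var(x) / tot
    theta <- theta + welch_band_power(x, cfg$fs, 4, 8) * scale / n_rep
    alpha <- alpha + welch_band_power(x, cfg$fs, 8, 13) * scale / n_rep
    beta <- beta + welch_band_power(x, cfg$fs, 13, 30) * scale / n_rep
  }
  # band windows also catch part of the 1/f background, so expect the
  # configured oscillation power plus a background share, within 35%
  bg_share <- function(lo, hi) {
    f <- seq(0.5, cfg$fs / 2, by = 0.01)
    dens <- f^(-cfg$background_exponent)
    cfg$background_power * sum(dens[f >= lo & f < hi]) / sum(dens)
  }
  expect_equal(theta, cfg$band_powers[["theta"]] + bg_share(4, 8),
               tolerance = 0.35)
  expect_equal(alpha, cfg$band_powers[["alpha"]] + bg_share(8, 13),
               tolerance = 0.35)
  expect_equal(beta, cfg$band_powers[["beta"]] + bg_share(13, 30),
               tolerance = 0.35)
})

test_that("write_cohort emits one TXT per session plus a ratings CSV", {
  coh <- generate_cohort(tiny_config())
  dest <- withr::local_tempdir()
  manifest <- write_cohort(coh, dest)
  expect_equal(sum(manifest$kind == "eeg_txt"), 6L)
  expect_equal(sum(manifest$kind == "ratings"), 1L)
  expect_true(all(file.exists(file.path(dest, manifest$file))))

  # lossless re-read
  s1 <- coh$sessions[[1]]
  back <- read_openbci_txt(file.path(dest,
                                     sprintf("%s_trial-%02d.txt",
                                             s1$subject_id, s1$trial_index)))
  expect_lt(max(abs(back$samples - s1$recording$samples)), 1e-4)
  rat <- read_ratings_csv(file.path(dest, "ratings.csv"))
  expect_equal(nrow(rat), 6L)
  expect_equal(rat$pleasure[1], s1$ratings$pleasure)
})

test_that("empty cohort writes nothing and returns an empty manifest", {
  coh <- structure(list(sessions = list(), config = tiny_config()),
                   class = "synthetic_cohort")
  dest <- withr::local_tempdir()
  manifest <- write_cohort(coh, dest)
  expect_equal(nrow(manifest), 0L)
  expect_length(list.files(dest), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_subjects = 0), "positive")
  expect_error(generator_config(fs = -1), "positive")
  expect_error(generator_config(montage = c("F3", "F3")), "unique")
  expect_error(generator_config(label_mix = c(positive = 0.5, negative = 0.5,
                                              excluded = 0.5)), "sum to 1")
  expect_error(generator_config(stratify = c(positive = 1L, negative = 1L,
                                             excluded = 1L)), "sum to 396")
})
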