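# Shared fixtures, built in code at test time.

# A small, fast generator configuration (2 subjects x 3 trials, full length);
# any generator_config() argument can be overridden.
tiny_config <- function(..., seed = 11L) {
  defaults <- list(n_subjects = 2L, n_trials_per_subject = 3L, seed = seed)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# Brute-force PS labeling oracle, written independently of label_ps():
# direct transcription of the two classification rules.
oracle_ps <- function(pleasure, stress) {
  if (pleasure > 0 && stress <= 1) {
    "positive"
  } else if (pleasure < 0 || stress > 2) {
    "negative"
  } else {
    "excluded"
  }
}

# |H(f)| of a digital filter evaluated from its polynomial coefficients —
# the analytic frequency-response oracle, independent of time-domain
# filtering.
response_mag <- function(coefs, f, fs) {
  w <- 2 * pi * f / fs
  zb <- exp(-1i * w * (seq_along(coefs$b) - 1))
  za <- exp(-1i * w * (seq_along(coefs$a) - 1))
  Mod(sum(coefs$b * zb) / sum(coefs$a * za))
}

# Welch-style band power oracle: averaged periodogram over 2-s windows,
# integrated over [lo, hi) Hz.
welch_band_power <- function(x, fs, lo, hi, win = 2 * fs) {
  n <- length(x)
  starts <- seq(1, n - win + 1, by = win %/% 2)
  psd <- 0
  for (s in starts) {
    seg <- x[s:(s + win - 1)] * 0.5 * (1 - cos(2 * pi * seq_len(win) / win))
    p <- Mod(stats::fft(seg))^2
    psd <- psd + p[seq_len(win %/% 2)]
  }
  psd <- psd / length(starts)
  freqs <- (seq_len(win %/% 2) - 1) * fs / win
  sum(psd[freqs >= lo & freqs < hi])
}

# instance array + labels with a trivially learnable mean-shift class
# difference, for fast engine tests
toy_instances <- function(n = 24L, timesteps = 20L, channels = 2L,
                          shift = 2, seed = 5L) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    set.seed(seed)
    on.exit(assign(".Random.seed", old, globalenv()))
    code
  }
  withr_seed({
    y <- rep(c("positive", "negative"), length.out = n)
    x <- array(stats::rnorm(n * timesteps * channels),
               dim = c(n, timesteps, channels))
    x[y == "positive", , 1] <- x[y == "positive", , 1] + shift
    list(x = x, y = one_hot(y), labels = y)
  })
}
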