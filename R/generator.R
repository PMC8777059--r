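#' Canonical 8-channel montage
#'
#' The dry-electrode montage used for conversation recording, in canonical
#' order: frontal F3/F4, lateral frontal F7/F8, temporal T7/T8, parieto-
#' occipital P3/P4 (10-20 system). Odd indices are left-hemisphere, even are
#' right.
#'
#' @return Character vector of 8 channel names.
#' @export
canonical_montage <- function() {
  c("F3", "F4", "F7", "F8", "T7", "T8", "P3", "P4")
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of the emulated study: cohort size,
#' acquisition parameters and the spectral composition of each trial. Every
#' channel is a sum of a 1/f background, band-limited theta/alpha/beta
#' oscillations, 60 Hz mains interference and slow baseline drift. The class
#' signal is a lateralized alpha-power asymmetry: for positive trials the
#' left-channel (F7, T7) vs right-channel (F8, T8) alpha-power log-ratio is
#' `+effect_size/2`, for negative trials `-effect_size/2` (so the two classes
#' differ by `effect_size`); trials destined for exclusion receive half the
#' effect with random sign.
#'
#' @param n_subjects number of subjects (default 11).
#' @param n_trials_per_subject conversation trials per subject (default 36).
#' @param fs sampling rate in Hz (default 250).
#' @param duration trial length in seconds (default 60).
#' @param montage ordered channel names (default [canonical_montage()]).
#' @param band_powers named numeric: target variance in uV^2 of the theta
#'   (4-8 Hz), alpha (8-13 Hz) and beta (13-30 Hz) oscillations.
#' @param background_power variance in uV^2 of the 1/f background.
#' @param background_exponent spectral slope of the background PSD
#'   (PSD proportional to 1/f^exponent).
#' @param line_noise_amp amplitude in uV of the 60 Hz mains component.
#' @param drift_amp amplitude in uV of the baseline drift.
#' @param drift_band frequency range in Hz of the drift sinusoid (must stay
#'   below 0.5 Hz).
#' @param effect_size class-conditional left-right alpha-power log-ratio
#'   difference (delta, dimensionless). Zero yields class-indistinguishable
#'   EEG by construction.
#' @param trial_band_sd between-trial lognormal jitter (SD on the log scale)
#'   of each band's power, shared across channels so the lateral ratio is
#'   preserved.
#' @param channel_band_sd additional per-channel lognormal power jitter.
#' @param label_mix target proportions of positive/negative/excluded trials.
#'   The default approximates the observed 126/69/201 composition of a
#'   396-trial cohort.
#' @param stratify optional named integer vector of exact class counts
#'   (positive, negative, excluded) summing to the total trial count; when
#'   given, labels are an exact shuffled multiset instead of i.i.d. draws.
#' @param seed RNG seed for [generate_cohort()].
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_subjects = 11L,
                             n_trials_per_subject = 36L,
                             fs = 250,
                             duration = 60,
                             montage = canonical_montage(),
                             band_powers = c(theta = 30, alpha = 60, beta = 20),
                             background_power = 100,
                             background_exponent = 1,
                             line_noise_amp = 5,
                             drift_amp = 20,
                             drift_band = c(0.05, 0.3),
                             effect_size = 1,
                             trial_band_sd = 0.15,
                             channel_band_sd = 0.05,
                             label_mix = c(positive = 0.32, negative = 0.17,
                                           excluded = 0.51),
                             stratify = NULL,
                             seed = 1L) {
  if (n_subjects < 1 || n_trials_per_subject < 1) {
    stop("n_subjects and n_trials_per_subject must be positive")
  }
  if (fs <= 0 || duration <= 0) stop("fs and duration must be positive")
  montage <- as.character(montage)
  if (anyDuplicated(montage)) stop("montage names must be unique")
  stopifnot(all(c("theta", "alpha", "beta") %in% names(band_powers)))
  if (abs(sum(label_mix) - 1) > 1e-8) stop("label_mix must sum to 1")
  stopifnot(all(names(label_mix) == c("positive", "negative", "excluded")))
  if (max(drift_band) >= 0.5) stop("drift_band must stay below 0.5 Hz")
  n_total <- n_subjects * n_trials_per_subject
  if (!is.null(stratify)) {
    stopifnot(all(sort(names(stratify)) ==
                    sort(c("positive", "negative", "excluded"))))
    if (sum(stratify) != n_total) {
      stop("stratify counts must sum to ", n_total, " trials")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_subject = as.integer(n_trials_per_subject),
                 fs = fs, duration = duration, montage = montage,
                 band_powers = band_powers,
                 background_power = background_power,
                 background_exponent = background_exponent,
                 line_noise_amp = line_noise_amp,
                 drift_amp = drift_amp, drift_band = drift_band,
                 effect_size = effect_size,
                 trial_band_sd = trial_band_sd,
                 channel_band_sd = channel_band_sd,
                 label_mix = label_mix, stratify = stratify,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

band_edges <- list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))

# 1/f^a shaped Gaussian noise with unit variance, by FFT amplitude shaping.
shaped_background <- function(n, fs, exponent) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)          # two-sided frequency axis
  w <- ifelse(f < 0.5, 0, f^(-exponent / 2))  # no DC/ultra-slow blow-up
  y <- Re(stats::fft(X * w, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Band-limited unit-variance oscillation: white noise through a Butterworth
# band-pass of the band edges.
band_oscillation <- function(n, coef) {
  pad <- 500L
  x <- stats::rnorm(n + pad)
  y <- signal::filter(coef, x)[(pad + 1L):(n + pad)]
  y / stats::sd(y)
}

band_filters <- function(fs) {
  lapply(band_edges, function(e) {
    signal::butter(2, e / (fs / 2), type = "pass")
  })
}

# Fraction of the 1/f^e background variance that falls in [lo, hi) Hz
# (the shaped spectrum is flat-zero below 0.5 Hz).
bg_band_share <- function(lo, hi, fs, exponent, floor_hz = 0.5) {
  I <- function(a, b) {
    if (abs(exponent - 1) < 1e-9) log(b / a)
    else (b^(1 - exponent) - a^(1 - exponent)) / (1 - exponent)
  }
  I(lo, hi) / I(floor_hz, fs / 2)
}

# Left/right alpha-oscillation scale factor r such that the *measured*
# in-band power ratio (oscillation + in-band background b) equals
# exp(log_ratio) when the left side carries a*r and the right side a/r.
alpha_lateral_scale <- function(a, b, log_ratio) {
  g <- exp(log_ratio)
  (-b * (1 - g) + sqrt(b^2 * (1 - g)^2 + 4 * a^2 * g)) / (2 * a)
}

#' Generate one trial of synthetic EEG
#'
#' Draws a single trial of band-structured multichannel EEG conditioned on an
#' emotion label (see [generator_config()] for the signal model). Consumes the
#' current R RNG stream; set `seed` for a self-contained deterministic draw.
#'
#' @param label one of `"positive"`, `"negative"`, `"excluded"`.
#' @param config a [generator_config()].
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return A [raw_recording()] with `fs * duration` samples per channel.
#' @export
generate_trial_eeg <- function(label, config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"),
            label %in% c("positive", "negative", "excluded"))
  if (!is.null(seed)) return(with_seed(seed, generate_trial_eeg(label, config)))
  fs <- config$fs
  n <- round(fs * config$duration)
  mont <- config$montage
  filters <- band_filters(fs)
  t_ax <- (seq_len(n) - 1) / fs

  delta <- config$effect_size
  log_ratio <- switch(label,
    positive = delta / 2,
    negative = -delta / 2,
    excluded = sample(c(-1, 1), 1L) * delta / 4)

  # between-trial band power jitter, shared across channels
  trial_jit <- stats::rlnorm(3, 0, config$trial_band_sd)
  names(trial_jit) <- names(band_edges)

  left <- c("F7", "T7")
  right <- c("F8", "T8")
  # lateral scaling compensates for the 1/f background power inside the
  # alpha window, so a Welch-periodogram alpha log-ratio recovers log_ratio
  bg_alpha <- config$background_power *
    bg_band_share(band_edges$alpha[1], band_edges$alpha[2], fs,
                  config$background_exponent)
  out <- matrix(0, n, length(mont))
  for (j in seq_along(mont)) {
    ch <- mont[j]
    sig <- sqrt(config$background_power) *
      shaped_background(n, fs, config$background_exponent)
    for (b in names(band_edges)) {
      pow <- config$band_powers[[b]] * trial_jit[[b]]
      if (b == "alpha" && (ch %in% left || ch %in% right)) {
        r <- alpha_lateral_scale(pow, bg_alpha, log_ratio)
        pow <- if (ch %in% left) pow * r else pow / r
      }
      pow <- pow * stats::rlnorm(1, 0, config$channel_band_sd)
      sig <- sig + sqrt(pow) * band_oscillation(n, filters[[b]])
    }
    sig <- sig + config$line_noise_amp *
      sin(2 * pi * 60 * t_ax + stats::runif(1, 0, 2 * pi))
    f0 <- stats::runif(1, config$drift_band[1], config$drift_band[2])
    sig <- sig + config$drift_amp *
      sin(2 * pi * f0 * t_ax + stats::runif(1, 0, 2 * pi))
    out[, j] <- sig
  }
  raw_recording(out, fs = fs, montage = mont,
                meta = list(label = label))
}

#' Generate a rating consistent with an emotion label
#'
#' Samples uniformly from the cells of the full (pleasure, arousal, stress)
#' grid whose pleasure/stress label equals `label`, so the draw re-labels to
#' `label` under [label_ps()] by construction (round-trip consistency). The
#' per-class cell sets are enumerated programmatically from [rating_grid()]:
#' 36 positive, 477 negative and 54 excluded cells.
#'
#' @param label one of `"positive"`, `"negative"`, `"excluded"`.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return A [ratings()] object.
#' @export
generate_ratings <- function(label, seed = NULL) {
  stopifnot(label %in% c("positive", "negative", "excluded"))
  if (!is.null(seed)) return(with_seed(seed, generate_ratings(label)))
  g <- rating_cells(label)
  i <- sample.int(nrow(g), 1L)
  ratings(g$pleasure[i], g$arousal[i], g$stress[i])
}

# memoized per-class cell sets
rating_cells <- local({
  cache <- NULL
  function(label) {
    if (is.null(cache)) cache <<- split(rating_grid(), rating_grid()$label)
    cache[[label]]
  }
})

#' Generate a full synthetic cohort
#'
#' Draws `n_subjects * n_trials_per_subject` sessions. Each session carries a
#' true emotion label (i.i.d. from `label_mix`, or an exact shuffled multiset
#' when `config$stratify` is set), a rating consistent with that label under
#' the pleasure/stress rule, and — when `signals = TRUE` — a synthetic EEG
#' trial conditioned on the label.
#'
#' @param config a [generator_config()].
#' @param signals generate the EEG waveforms (default `TRUE`). With `FALSE`
#'   only labels and ratings are drawn, which is cheap and sufficient for
#'   labeling-scheme and cohort-composition work.
#' @return An object of class `"synthetic_cohort"`: a list with `sessions`
#'   (each session a list with `subject_id`, `trial_index`, `recording`,
#'   `ratings`, `true_label`) and the `config`.
#' @export
generate_cohort <- function(config = generator_config(), signals = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n_total <- config$n_subjects * config$n_trials_per_subject
    classes <- c("positive", "negative", "excluded")
    if (is.null(config$stratify)) {
      labels <- sample(classes, n_total, replace = TRUE,
                       prob = config$label_mix[classes])
    } else {
      labels <- sample(rep(classes, times = config$stratify[classes]))
    }
    sessions <- vector("list", n_total)
    k <- 0L
    for (s in seq_len(config$n_subjects)) {
      for (tr in seq_len(config$n_trials_per_subject)) {
        k <- k + 1L
        lab <- labels[k]
        sessions[[k]] <- list(
          subject_id = sprintf("s%02d", s),
          trial_index = tr,
          recording = if (signals) generate_trial_eeg(lab, config) else NULL,
          ratings = generate_ratings(lab),
          true_label = lab)
      }
    }
    structure(list(sessions = sessions, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  labs <- vapply(x$sessions, `[[`, character(1), "true_label")
  cat(sprintf("<synthetic_cohort> %d sessions (%d subjects x %d trials)\n",
              length(x$sessions), x$config$n_subjects,
              x$config$n_trials_per_subject))
  print(table(factor(labs, levels = c("positive", "negative", "excluded"))))
  invisible(x)
}

#' @export
length.synthetic_cohort <- function(x) length(x$sessions)

#' Ratings table of a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame with the [read_ratings_csv()] schema.
#' @export
cohort_ratings <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  do.call(rbind, lapply(cohort$sessions, function(s) {
    data.frame(subject_id = s$subject_id, trial_index = s$trial_index,
               pleasure = s$ratings$pleasure, arousal = s$ratings$arousal,
               stress = s$ratings$stress)
  }))
}

#' Write a cohort to disk
#'
#' Emits one OpenBCI-dialect TXT recording per session plus a single ratings
#' CSV, re-readable by [read_openbci_txt()] and [read_ratings_csv()] with a
#' lossless round-trip of samples and ratings.
#'
#' @param cohort a [generate_cohort()] result with signals.
#' @param destination directory (created if absent).
#' @return Invisibly, a manifest data.frame with columns `file`, `kind`,
#'   `subject_id`, `trial_index`.
#' @export
write_cohort <- function(cohort, destination) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!length(cohort$sessions)) {
    return(invisible(data.frame(file = character(), kind = character(),
                                subject_id = character(),
                                trial_index = integer())))
  }
  if (!dir.exists(destination)) {
    ok <- dir.create(destination, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create destination directory: ", destination)
  }
  rows <- lapply(cohort$sessions, function(s) {
    if (is.null(s$recording)) {
      stop("session ", s$subject_id, "/", s$trial_index,
           " has no recording; generate the cohort with signals = TRUE")
    }
    fn <- sprintf("%s_trial-%02d.txt", s$subject_id, s$trial_index)
    write_openbci_txt(s$recording, file.path(destination, fn))
    data.frame(file = fn, kind = "eeg_txt",
               subject_id = s$subject_id, trial_index = s$trial_index)
  })
  write_ratings_csv(cohort_ratings(cohort), file.path(destination,
                                                      "ratings.csv"))
  manifest <- rbind(do.call(rbind, rows),
                    data.frame(file = "ratings.csv", kind = "ratings",
                               subject_id = NA, trial_index = NA))
  invisible(manifest)
}
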