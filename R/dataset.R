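#' Named channel subsets of the canonical montage
#'
#' `"full"` is the whole 8-channel montage; `"eyewear"` keeps the four
#' channels near the ears (F7, F8, T7, T8 — the positions a sensing eyewear
#' frame could reach); `"headband"` keeps the four frontal channels
#' (F3, F4, F7, F8). Order always follows the canonical montage.
#'
#' @param name `"full"`, `"eyewear"` or `"headband"`, or a character vector of
#'   channel names drawn from the canonical montage.
#' @return Character vector of channel names.
#' @export
channel_subset <- function(name = "full") {
  if (length(name) == 1L && name %in% c("full", "eyewear", "headband")) {
    sel <- switch(name,
                  full = canonical_montage(),
                  eyewear = c("F7", "F8", "T7", "T8"),
                  headband = c("F3", "F4", "F7", "F8"))
  } else {
    bad <- setdiff(name, canonical_montage())
    if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
    sel <- name
  }
  # canonical order, no duplicates
  canonical_montage()[canonical_montage() %in% sel]
}

#' Cut one trial into contiguous 3-second segments
#'
#' Partitions a full-length trial (exactly `fs * 60` samples per channel) into
#' `n_segments` contiguous, non-overlapping, ordered windows. Concatenating
#' the segments reconstructs the trial exactly; a trial of any other length is
#' an error — never silently truncated or padded.
#'
#' @param samples timepoints x channels matrix (or a [raw_recording()]).
#' @param fs sampling rate in Hz (taken from the recording when one is given).
#' @param segment_s segment length in seconds (default 3).
#' @param n_segments number of segments (default 20).
#' @return Array of dim `(n_segments, segment_s * fs, channels)`.
#' @export
segment_trial <- function(samples, fs = 250, segment_s = 3, n_segments = 20) {
  if (inherits(samples, "raw_recording")) {
    fs <- samples$fs
    samples <- samples$samples
  }
  samples <- as.matrix(samples)
  len <- round(fs * segment_s)
  need <- len * n_segments
  if (nrow(samples) != need) {
    stop("trial has ", nrow(samples), " samples; expected exactly ", need,
         " (", n_segments, " x ", segment_s, " s x ", fs, " Hz)")
  }
  nch <- ncol(samples)
  out <- array(0, dim = c(n_segments, len, nch))
  for (g in seq_len(n_segments)) {
    out[g, , ] <- samples[((g - 1L) * len + 1L):(g * len), , drop = FALSE]
  }
  out
}

#' One-hot encode positive/negative labels
#'
#' Column 1 encodes positive, column 2 negative; each row sums to 1. An
#' excluded label is an error — exclusion happens before assembly.
#'
#' @param labels character vector over `{"positive", "negative"}`.
#' @return `length(labels) x 2` numeric matrix with columns
#'   `c("positive", "negative")`.
#' @export
one_hot <- function(labels) {
  bad <- setdiff(unique(labels), c("positive", "negative"))
  if (length(bad)) {
    stop("labels must be positive/negative; got: ", paste(bad, collapse = ", "))
  }
  m <- cbind(positive = as.numeric(labels == "positive"),
             negative = as.numeric(labels == "negative"))
  rownames(m) <- NULL
  m
}

#' Assemble a segmented, labeled dataset from a cohort
#'
#' Runs the dataset-building stage: label every session from its ratings
#' under the pleasure/stress rule, drop excluded sessions, restrict to a
#' channel subset, segment every retained trial and one-hot the labels. The
#' result is the trials x segments x timesteps x channels tensor the
#' classifiers consume (full montage at 250 Hz: `n x 20 x 750 x 8`).
#'
#' @param cohort a preprocessed [generate_cohort()] result (with signals).
#' @param subset montage subset name or channel vector ([channel_subset()]).
#' @param labels optional character vector of labels, one per session,
#'   overriding PS labeling of the stored ratings (used e.g. to assemble from
#'   generator truth).
#' @param segment_s,n_segments segmentation geometry (default 3 s x 20).
#' @return An object of class `"segmented_dataset"`: list with `data` (4-d
#'   array), `labels` (n x 2 one-hot), `trial_ids` (character provenance
#'   keys), `montage`, `fs`.
#' @export
assemble_dataset <- function(cohort, subset = "full", labels = NULL,
                             segment_s = 3, n_segments = 20) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  mont <- channel_subset(subset)
  sess <- cohort$sessions
  if (is.null(labels)) {
    labels <- vapply(sess, function(s) label_ps(s$ratings), character(1))
  }
  stopifnot(length(labels) == length(sess))
  keep <- which(labels %in% c("positive", "negative"))
  fs <- cohort$config$fs
  len <- round(fs * segment_s)

  data <- array(0, dim = c(length(keep), n_segments, len, length(mont)))
  ids <- character(length(keep))
  for (i in seq_along(keep)) {
    s <- sess[[keep[i]]]
    if (is.null(s$recording)) {
      stop("session ", s$subject_id, "/", s$trial_index, " has no signal")
    }
    chan_idx <- match(mont, s$recording$montage)
    if (anyNA(chan_idx)) {
      stop("montage of ", s$subject_id, "/", s$trial_index,
           " lacks channel(s): ", paste(mont[is.na(chan_idx)], collapse = ", "))
    }
    seg <- tryCatch(
      segment_trial(s$recording$samples[, chan_idx, drop = FALSE], fs = fs,
                    segment_s = segment_s, n_segments = n_segments),
      error = function(e) stop("trial ", s$subject_id, "/", s$trial_index,
                               ": ", conditionMessage(e), call. = FALSE))
    data[i, , , ] <- seg
    ids[i] <- paste0(s$subject_id, "/", s$trial_index)
  }
  lab <- if (length(keep)) one_hot(labels[keep]) else
    matrix(0, 0, 2, dimnames = list(NULL, c("positive", "negative")))
  structure(list(data = data, labels = lab, trial_ids = ids,
                 montage = mont, fs = fs),
            class = "segmented_dataset")
}

#' @export
print.segmented_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("<segmented_dataset> %d trials x %d segments x %d",
                     " timesteps x %d channels\n"), d[1], d[2], d[3], d[4]))
  cat(sprintf("  labels: %d positive, %d negative; montage: %s\n",
              sum(x$labels[, "positive"]), sum(x$labels[, "negative"]),
              paste(x$montage, collapse = ", ")))
  invisible(x)
}

#' @export
dim.segmented_dataset <- function(x) dim(x$data)

# Flatten a segmented dataset to model instances: one 3-s segment per
# instance, each inheriting its trial's label. Returns list(x = instances x
# timesteps x channels, y = instances x 2, trial_of = instance -> trial row).
flatten_instances <- function(ds, trial_rows = seq_len(dim(ds$data)[1])) {
  d <- dim(ds$data)
  n_seg <- d[2]
  n <- length(trial_rows) * n_seg
  x <- array(0, dim = c(n, d[3], d[4]))
  trial_of <- integer(n)
  k <- 0L
  for (tr in trial_rows) {
    x[(k + 1L):(k + n_seg), , ] <- ds$data[tr, , , ]
    trial_of[(k + 1L):(k + n_seg)] <- tr
    k <- k + n_seg
  }
  list(x = x, y = ds$labels[trial_of, , drop = FALSE], trial_of = trial_of)
}
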