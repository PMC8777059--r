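#' Construct a raw multichannel EEG recording
#'
#' The in-memory form of one trial: a channels-in-columns numeric matrix of
#' sample values in microvolts, the sampling rate, the ordered montage, the
#' per-row acquisition counter and any header metadata.
#'
#' @param samples numeric matrix, timepoints x channels, in microvolts.
#' @param fs sampling rate in Hz.
#' @param montage character vector of channel names, one per column.
#' @param sample_index integer acquisition counter, one per row (defaults to
#'   `0:(n-1)` as emitted by the acquisition board).
#' @param meta named list of free-form header key/values.
#' @return An object of class `"raw_recording"`.
#' @export
raw_recording <- function(samples, fs, montage,
                          sample_index = NULL, meta = list()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number")
  }
  montage <- as.character(montage)
  if (ncol(samples) != length(montage)) {
    stop("montage length (", length(montage),
         ") must equal channel count (", ncol(samples), ")")
  }
  if (anyDuplicated(montage)) stop("montage names must be unique")
  if (is.null(sample_index)) sample_index <- seq_len(nrow(samples)) - 1L
  if (length(sample_index) != nrow(samples)) {
    stop("sample_index length must equal the number of timepoints")
  }
  colnames(samples) <- montage
  structure(list(samples = samples, fs = fs, montage = montage,
                 sample_index = as.integer(sample_index), meta = meta),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat("  montage:", paste(x$montage, collapse = ", "), "\n")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
dim.raw_recording <- function(x) dim(x$samples)

# The TXT dialect written by the acquisition GUI: '%'-prefixed header lines,
# then comma-separated rows of (sample_index, ch1..chN[, extras...]). Extra
# trailing columns (aux channels, timestamps) are ignored with a warning.

#' Read an OpenBCI-GUI-dialect TXT recording
#'
#' Parses the plain-text export of the acquisition GUI: leading header lines
#' prefixed with `%` are collected into `meta`; every remaining line is a
#' comma-separated data row whose first field is the sample counter and whose
#' next `n_channels` fields are channel values in microvolts.
#'
#' @param path path to the TXT file.
#' @param n_channels number of EEG channels to read (default 8).
#' @param montage channel names; defaults to the canonical 8-channel montage
#'   (truncated to `n_channels`).
#' @param fs sampling-rate override; when `NULL` the rate is taken from a
#'   `Sample Rate = <x> Hz` header line (error if absent).
#' @return A [raw_recording()].
#' @export
read_openbci_txt <- function(path, n_channels = 8L, montage = NULL,
                             fs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "%")
  # header must be a leading block
  n_hdr <- if (any(!is_hdr)) which(!is_hdr)[1] - 1L else length(lines)
  hdr <- lines[seq_len(n_hdr)]
  body <- lines[setdiff(seq_along(lines), seq_len(n_hdr))]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("empty data section in ", path)

  meta <- parse_txt_header(hdr)
  if (is.null(fs)) {
    fs <- header_sample_rate(meta)
    if (is.null(fs)) stop("no 'Sample Rate' header in ", path,
                          " and no fs override given")
  }

  fields <- strsplit(body, ",", fixed = TRUE)
  ncols <- lengths(fields)
  need <- n_channels + 1L
  bad <- which(ncols < need)
  if (length(bad)) {
    stop("line ", n_hdr + bad[1], " of ", path, " has ", ncols[bad[1]],
         " fields; expected at least ", need,
         " (sample index + ", n_channels, " channels)")
  }
  if (any(ncols > need)) {
    warning("ignoring ", max(ncols) - need,
            " extra trailing column(s) in ", path)
  }
  # coercion NAs are detected and reported with their line number below
  flat <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[seq_len(need)]), numeric(need)))
  if (anyNA(flat)) {
    bad_row <- which(apply(is.na(flat), 2, any))[1]
    stop("malformed numeric field at line ", n_hdr + bad_row, " of ", path)
  }
  m <- t(flat)
  if (is.null(montage)) montage <- canonical_montage()[seq_len(n_channels)]
  raw_recording(m[, -1L, drop = FALSE], fs = fs, montage = montage,
                sample_index = as.integer(m[, 1L]), meta = meta)
}

parse_txt_header <- function(hdr) {
  meta <- list()
  for (h in hdr) {
    h <- sub("^%+\\s*", "", h)
    if (!nzchar(h)) next
    if (grepl("=", h, fixed = TRUE)) {
      kv <- strsplit(h, "=", fixed = TRUE)[[1]]
      meta[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    } else {
      meta[[length(meta) + 1L]] <- h
    }
  }
  meta
}

header_sample_rate <- function(meta) {
  nm <- names(meta)
  hit <- which(grepl("sample\\s*rate", nm, ignore.case = TRUE))
  if (!length(hit)) return(NULL)
  as.numeric(sub("^([0-9.]+).*", "\\1", meta[[hit[1]]]))
}

#' Write a recording in the OpenBCI-GUI TXT dialect
#'
#' @param rec a [raw_recording()].
#' @param path destination file.
#' @param digits significant digits for sample values (default 9, enough for a
#'   lossless round-trip at microvolt scale).
#' @return `path`, invisibly.
#' @export
write_openbci_txt <- function(rec, path, digits = 9L) {
  stopifnot(inherits(rec, "raw_recording"))
  hdr <- c("%OpenBCI Raw EEG Data",
           sprintf("%%Number of channels = %d", ncol(rec$samples)),
           sprintf("%%Sample Rate = %g Hz", rec$fs))
  dt <- data.table::as.data.table(signif(rec$samples, digits))
  dt <- cbind(data.table::data.table(V0 = rec$sample_index), dt)
  writeLines(hdr, path)
  data.table::fwrite(dt, path, col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Write a recording as plain CSV
#'
#' One row per timepoint, one column per channel; the header row carries the
#' montage names. This is the working format downstream of TXT conversion.
#'
#' @param rec a [raw_recording()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  dt <- data.table::as.data.table(rec$samples)
  data.table::setnames(dt, rec$montage)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a plain-CSV recording
#'
#' @param path CSV written by [write_recording_csv()].
#' @param fs sampling rate in Hz (CSV carries no header metadata; default 250).
#' @return A [raw_recording()].
#' @export
read_recording_csv <- function(path, fs = 250) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path)
  raw_recording(as.matrix(dt), fs = fs, montage = names(dt))
}

#' Read and validate a per-trial ratings table
#'
#' Expects columns `subject_id`, `trial_index`, `pleasure`, `arousal`,
#' `stress`. Every row is range-validated (pleasure, arousal in `[-4, 4]`;
#' stress in `[1, 7]`; all integer) and `(subject_id, trial_index)` must be
#' unique.
#'
#' @param path CSV file.
#' @return A data.frame of validated rows.
#' @export
read_ratings_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- as.data.frame(data.table::fread(path))
  need <- c("subject_id", "trial_index", "pleasure", "arousal", "stress")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ratings table missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(df$subject_id, df$trial_index)
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, trial_index): ", key[anyDuplicated(key)])
  }
  for (i in seq_len(nrow(df))) {
    validate_rating_values(df$pleasure[i], df$arousal[i], df$stress[i],
                           where = paste0("row ", i))
  }
  df
}

#' Write a ratings table
#'
#' @param table data.frame with the [read_ratings_csv()] schema.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(table, path) {
  data.table::fwrite(data.table::as.data.table(table), path)
  invisible(path)
}
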