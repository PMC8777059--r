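#' Construct a validated self-assessment rating
#'
#' A rating holds the three per-trial self-assessment values collected after
#' each one-minute conversation: pleasure (valence) and arousal on nine-point
#' integer scales from -4 ("not at all") to 4 ("extremely"), and stress on a
#' seven-point integer scale from 1 ("no stress at all") to 7 ("extremely").
#'
#' @param pleasure integer in `[-4, 4]`.
#' @param arousal integer in `[-4, 4]`.
#' @param stress integer in `[1, 7]`.
#' @return A named list of class `"ratings"`.
#' @examples
#' ratings(pleasure = 2, arousal = 0, stress = 1)
#' @export
ratings <- function(pleasure, arousal, stress) {
  validate_rating_values(pleasure, arousal, stress)
  structure(list(pleasure = as.integer(pleasure),
                 arousal = as.integer(arousal),
                 stress = as.integer(stress)),
            class = "ratings")
}

validate_rating_values <- function(pleasure, arousal, stress, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(" (", where, ")")
  chk <- function(x, lo, hi, nm) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) ||
        x < lo || x > hi) {
      stop(nm, " must be a single integer in [", lo, ", ", hi, "], got ",
           deparse(substitute(x)), " = ", format(x), ctx, call. = FALSE)
    }
  }
  chk(pleasure, -4L, 4L, "pleasure")
  chk(arousal, -4L, 4L, "arousal")
  chk(stress, 1L, 7L, "stress")
  invisible(TRUE)
}

#' @export
print.ratings <- function(x, ...) {
  cat(sprintf("<ratings> pleasure = %d, arousal = %d, stress = %d\n",
              x$pleasure, x$arousal, x$stress))
  invisible(x)
}

#' Pleasure/stress (PS) emotion labeling
#'
#' Maps a self-assessment rating to an emotion class under the pleasure/stress
#' rule used for the two-class EEG dataset:
#' \describe{
#'   \item{positive}{pleasure > 0 and stress <= 1 (i.e. stress at the scale
#'     minimum, 1);}
#'   \item{negative}{pleasure < 0 or stress > 2;}
#'   \item{excluded}{anything else — these trials are dropped before dataset
#'     assembly.}
#' }
#' The two rules are disjoint: positive requires pleasure > 0 and stress = 1,
#' either of which is incompatible with the negative rule.
#'
#' @param r a [ratings()] object, or anything coercible via its
#'   `pleasure`/`stress` fields (a one-row list works).
#' @return One of `"positive"`, `"negative"`, `"excluded"` (character).
#' @examples
#' label_ps(ratings(2, 0, 1))   # "positive"
#' label_ps(ratings(1, 0, 5))   # "negative"
#' label_ps(ratings(3, 1, 2))   # "excluded"
#' @seealso [va_quadrant()], [summarize_labels()]
#' @export
label_ps <- function(r) {
  p <- r$pleasure
  s <- r$stress
  if (is.null(p) || is.null(s)) stop("ratings must carry pleasure and stress")
  if (p > 0 && s <= 1) return("positive")
  if (p < 0 || s > 2) return("negative")
  "excluded"
}

#' Valence-arousal quadrant of a rating
#'
#' Places a (pleasure, arousal) pair in the two-dimensional valence-arousal
#' emotion space. Strict sign tests are used; any rating on an axis
#' (pleasure = 0 or arousal = 0) is `"on_axis"` and is not assigned an emotion.
#'
#' @param p pleasure (valence), integer in `[-4, 4]`.
#' @param a arousal, integer in `[-4, 4]`.
#' @return One of `"happy"` (quadrant I), `"frightened"` (II), `"boredom"`
#'   (III), `"relaxed"` (IV) or `"on_axis"`.
#' @examples
#' va_quadrant(3, 2)    # "happy"
#' va_quadrant(-1, -1)  # "boredom"
#' va_quadrant(0, 4)    # "on_axis"
#' @export
va_quadrant <- function(p, a) {
  stopifnot(length(p) == 1L, length(a) == 1L,
            p >= -4, p <= 4, a >= -4, a <= 4)
  if (p == 0 || a == 0) return("on_axis")
  if (p > 0 && a > 0) return("happy")
  if (p < 0 && a > 0) return("frightened")
  if (p < 0 && a < 0) return("boredom")
  "relaxed"
}

#' Tabulate emotion labels over a ratings table
#'
#' Applies both labeling schemes to every row of a ratings table and returns
#' the class counts. The PS counts partition the table into
#' positive/negative/excluded; the VA counts partition it into the four
#' quadrants plus the axis.
#'
#' @param table a data.frame as returned by [read_ratings_csv()], with columns
#'   `pleasure`, `arousal`, `stress`.
#' @return A list with components `n` (row count), `ps` (named integer vector
#'   over positive/negative/excluded) and `va` (named integer vector over
#'   happy/frightened/boredom/relaxed/on_axis).
#' @export
summarize_labels <- function(table) {
  stopifnot(is.data.frame(table))
  ps_levels <- c("positive", "negative", "excluded")
  va_levels <- c("happy", "frightened", "boredom", "relaxed", "on_axis")
  n <- nrow(table)
  if (n == 0L) {
    ps <- stats::setNames(integer(length(ps_levels)), ps_levels)
    va <- stats::setNames(integer(length(va_levels)), va_levels)
    return(list(n = 0L, ps = ps, va = va))
  }
  ps_lab <- vapply(seq_len(n), function(i) {
    label_ps(list(pleasure = table$pleasure[i], stress = table$stress[i]))
  }, character(1))
  va_lab <- vapply(seq_len(n), function(i) {
    va_quadrant(table$pleasure[i], table$arousal[i])
  }, character(1))
  list(n = n,
       ps = table(factor(ps_lab, levels = ps_levels)) |> c(),
       va = table(factor(va_lab, levels = va_levels)) |> c())
}

#' Enumerate the full rating grid with PS labels
#'
#' All 9 x 9 x 7 = 567 combinations of (pleasure, arousal, stress) with the PS
#' label of each cell. Used by the synthetic generator to sample ratings
#' uniformly from the cells of a requested class, and by tests as the domain
#' for the brute-force labeling oracle.
#'
#' @return A data.frame with columns `pleasure`, `arousal`, `stress`, `label`.
#' @export
rating_grid <- function() {
  g <- expand.grid(pleasure = -4:4, arousal = -4:4, stress = 1:7,
                   KEEP.OUT.ATTRS = FALSE)
  g$label <- vapply(seq_len(nrow(g)), function(i) {
    label_ps(list(pleasure = g$pleasure[i], stress = g$stress[i]))
  }, character(1))
  g
}
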