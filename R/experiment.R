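#' Random trial-level fold assignment
#'
#' Partitions trials into `k` near-equal random folds (sizes differ by at
#' most one; larger folds come first). Folds are cut at the trial level so
#' that all 20 segments of a trial share a fold — validating on whole trials
#' prevents segment-level leakage while matching the printed split sizes
#' (195 trials, k = 4: validation fold of 49, training set of 146 for three
#' of the four rotations).
#'
#' @param n_trials number of trials.
#' @param k number of folds (default 4).
#' @param seed shuffle seed.
#' @return An object of class `"fold_assignment"`: list with `k`, `fold`
#'   (integer fold id per trial) and `seed`.
#' @export
make_folds <- function(n_trials, k = 4L, seed = 1L) {
  if (n_trials < k) stop("need at least k = ", k, " trials, got ", n_trials)
  sizes <- rep(n_trials %/% k, k)
  extra <- n_trials %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- integer(n_trials)
  with_seed(seed, {
    fold[sample.int(n_trials)] <- rep(seq_len(k), times = sizes)
  })
  structure(list(k = as.integer(k), fold = fold, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> %d trials in %d folds (sizes %s)\n",
              length(x$fold), x$k,
              paste(tabulate(x$fold, x$k), collapse = ", ")))
  invisible(x)
}

#' Epoch selection over per-fold early-stopping epochs
#'
#' The cross-validation protocol's epoch rule: the selected training length
#' is the maximum of the per-fold early-stopping epochs T1..Tk.
#'
#' @param Ts non-empty vector of per-fold epoch counts.
#' @return `max(Ts)`.
#' @export
select_epoch <- function(Ts) {
  if (!length(Ts)) stop("Ts must be non-empty")
  max(Ts)
}

#' Trial-level majority vote over segment predictions
#'
#' Aggregates segment-level class predictions to one prediction per trial by
#' majority vote; ties break toward `"positive"`. All trials must carry the
#' same number of segment predictions.
#'
#' @param predictions character vector of segment-level predicted labels.
#' @param trial_ids parallel vector identifying each segment's trial.
#' @param truth optional named vector (or plain vector in trial order) of
#'   true per-trial labels; when given, trial-level accuracy is computed.
#' @return list with `predicted` (named character, one per trial) and
#'   `accuracy` (`NA` unless `truth` given).
#' @export
trial_majority_vote <- function(predictions, trial_ids, truth = NULL) {
  stopifnot(length(predictions) == length(trial_ids))
  counts <- table(trial_ids)
  if (length(unique(counts)) > 1L) {
    stop("unequal segment counts per trial: ",
         paste(range(counts), collapse = " vs "))
  }
  split_pred <- split(predictions, trial_ids)
  predicted <- vapply(split_pred, function(p) {
    npos <- sum(p == "positive")
    if (npos >= length(p) / 2) "positive" else "negative"
  }, character(1))
  acc <- NA_real_
  if (!is.null(truth)) {
    if (!is.null(names(truth))) truth <- truth[names(predicted)]
    acc <- mean(predicted == truth)
  }
  list(predicted = predicted, accuracy = acc)
}

fold_instances <- function(ds, trial_rows) {
  fl <- flatten_instances(ds, trial_rows)
  fl
}

#' Fourfold cross-validation with early stopping and epoch re-selection
#'
#' Runs the two-phase protocol on a segmented dataset:
#' \enumerate{
#'   \item Phase 1 — for each of `k` trial-level folds, train on the other
#'     folds' segments with validation-loss early stopping (patience 2,
#'     min-delta 0), yielding per-fold stopping epochs T1..Tk.
#'   \item Epoch selection — the training length is `max(T1..Tk)`.
#'   \item Phase 2 — retrain each fold for exactly the selected epoch count
#'     (no early stopping) and record its validation accuracy.
#' }
#' Segment-level accuracy is the primary metric; trial-level majority-vote
#' accuracy is recorded alongside. Training/validation trial sets are
#' verified disjoint in every fold.
#'
#' @param dataset a `segmented_dataset` with both classes present.
#' @param spec a [model_spec()] (input geometry checked against the data).
#' @param control a [train_control()]; `max_epochs` caps phase 1.
#' @param k folds (default 4).
#' @param two_phase run the fixed-epoch retraining phase (default `TRUE`);
#'   with `FALSE` the phase-1 early-stopped accuracies are reported.
#' @return An object of class `"cv_result"`: per-fold accuracies (both
#'   phases and both granularities), `T` (= T1..Tk), `selected_epoch`,
#'   `mean_accuracy` (mean of reported per-fold segment accuracies),
#'   `trial_accuracy`, per-fold histories and the fold assignment.
#' @export
run_cv <- function(dataset, spec = model_spec(), control = train_control(),
                   k = 4L, two_phase = TRUE) {
  stopifnot(inherits(dataset, "segmented_dataset"))
  n_trials <- dim(dataset$data)[1]
  if (n_trials == 0L) stop("empty dataset")
  if (length(unique(max.col(dataset$labels))) < 2L) {
    stop("dataset must contain both classes")
  }
  folds <- make_folds(n_trials, k = k, seed = control$seed)
  trial_truth <- c("positive", "negative")[max.col(dataset$labels,
                                                   ties.method = "first")]

  Ts <- integer(k)
  hist1 <- vector("list", k)
  acc1 <- numeric(k)
  for (i in seq_len(k)) {
    val_rows <- which(folds$fold == i)
    train_rows <- which(folds$fold != i)
    stopifnot(length(intersect(val_rows, train_rows)) == 0L,
              length(union(val_rows, train_rows)) == n_trials)
    tr <- fold_instances(dataset, train_rows)
    va <- fold_instances(dataset, val_rows)
    ctl <- control
    ctl$early_stopping <- TRUE
    ctl$seed <- control$seed + 1000L * i
    fit <- eeg_classifier(tr$x, tr$y, spec = spec, control = ctl,
                          validation = list(x = va$x, y = va$y))
    Ts[i] <- fit$epochs_run
    hist1[[i]] <- fit$history
    acc1[i] <- fit$history$val_accuracy[fit$epochs_run]
  }
  selected <- select_epoch(Ts)

  acc2 <- rep(NA_real_, k)
  trial_acc <- rep(NA_real_, k)
  loss2 <- rep(NA_real_, k)
  hist2 <- vector("list", k)
  if (two_phase) {
    for (i in seq_len(k)) {
      val_rows <- which(folds$fold == i)
      train_rows <- which(folds$fold != i)
      tr <- fold_instances(dataset, train_rows)
      va <- fold_instances(dataset, val_rows)
      ctl <- control
      ctl$early_stopping <- FALSE
      ctl$max_epochs <- selected
      ctl$seed <- control$seed + 1000L * i
      fit <- eeg_classifier(tr$x, tr$y, spec = spec, control = ctl,
                            validation = list(x = va$x, y = va$y))
      h <- fit$history
      acc2[i] <- h$val_accuracy[nrow(h)]
      loss2[i] <- h$val_loss[nrow(h)]
      hist2[[i]] <- h
      seg_pred <- predict(fit, va$x, type = "class")
      mv <- trial_majority_vote(seg_pred, va$trial_of,
                                truth = stats::setNames(
                                  trial_truth[val_rows],
                                  unique(va$trial_of)))
      trial_acc[i] <- mv$accuracy
    }
  }
  reported <- if (two_phase) acc2 else acc1
  structure(list(k = k, folds = folds, T = Ts, selected_epoch = selected,
                 fold_accuracies = reported,
                 early_stop_accuracies = acc1,
                 fixed_epoch_accuracies = acc2,
                 final_val_loss = loss2,
                 mean_accuracy = mean(reported),
                 trial_accuracy = mean(trial_acc),
                 trial_fold_accuracies = trial_acc,
                 histories = list(phase1 = hist1, phase2 = hist2),
                 spec = spec, control = control),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV, %s (%s, lr %g)\n", x$k,
              toupper(x$spec$architecture), x$control$optimizer,
              x$control$learning_rate))
  cat(sprintf("  early-stop epochs T = (%s); selected epoch = %d\n",
              paste(x$T, collapse = ", "), x$selected_epoch))
  cat(sprintf("  fold segment accuracies: %s\n",
              paste(sprintf("%.3f", x$fold_accuracies), collapse = ", ")))
  cat(sprintf("  mean segment accuracy %.3f; trial majority-vote %.3f\n",
              x$mean_accuracy, x$trial_accuracy))
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  print(object)
  cat("\nPer-fold detail (phase 2, fixed epochs):\n")
  print(data.frame(fold = seq_len(object$k), T = object$T,
                   segment_accuracy = object$fixed_epoch_accuracies,
                   trial_accuracy = object$trial_fold_accuracies,
                   final_val_loss = object$final_val_loss),
        row.names = FALSE)
  invisible(object)
}

#' Optimizer x learning-rate grid of cross-validated runs
#'
#' Runs [run_cv()] for every (optimizer, learning rate) cell and reports a
#' results table in the style of the model-comparison table: mean accuracy
#' and selected epoch per cell, with a cell flagged (dash, accuracy
#' suppressed) when its final validation loss exceeds 1 or it hits 100%
#' validation accuracy within very few (`overfit_epochs`) epochs —
#' symptoms of a non-converged or overfitted run.
#'
#' @param dataset a `segmented_dataset`.
#' @param spec a [model_spec()].
#' @param optimizers character subset of sgd/rmsprop/adam.
#' @param learning_rates numeric vector (default `c(0.01, 0.001, 0.0001)`).
#' @param control base [train_control()]; optimizer/learning rate are
#'   overridden per cell.
#' @param k folds.
#' @param overfit_epochs the "very few epochs" bound of the overfit flag
#'   (default 5).
#' @param dataset_name label for the report rows.
#' @return An object of class `"grid_result"` wrapping a data.frame with one
#'   row per cell: dataset, montage, architecture, optimizer, learning_rate,
#'   mean_accuracy, epoch, overfit, and the underlying `cv` list.
#' @export
run_grid <- function(dataset, spec = model_spec(),
                     optimizers = c("sgd", "rmsprop", "adam"),
                     learning_rates = c(0.01, 0.001, 0.0001),
                     control = train_control(), k = 4L,
                     overfit_epochs = 5L,
                     dataset_name = "dataset") {
  cells <- expand.grid(optimizer = optimizers, lr = learning_rates,
                       stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  cvs <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ctl <- control
    ctl$optimizer <- cells$optimizer[i]
    ctl$learning_rate <- cells$lr[i]
    cv <- run_cv(dataset, spec = spec, control = ctl, k = k)
    flagged <- overfit_flag(cv, overfit_epochs)
    rows[[i]] <- data.frame(
      dataset = dataset_name,
      montage = paste(dataset$montage, collapse = ","),
      architecture = spec$architecture,
      optimizer = cells$optimizer[i],
      learning_rate = cells$lr[i],
      mean_accuracy = if (flagged) NA_real_ else cv$mean_accuracy,
      epoch = cv$selected_epoch,
      overfit = flagged)
    cvs[[i]] <- cv
  }
  structure(list(table = do.call(rbind, rows), cv = cvs),
            class = "grid_result")
}

overfit_flag <- function(cv, overfit_epochs = 5L) {
  final_loss <- cv$final_val_loss
  if (all(is.na(final_loss))) {
    final_loss <- vapply(cv$histories$phase1, function(h)
      h$val_loss[nrow(h)], numeric(1))
  }
  mean(final_loss, na.rm = TRUE) > 1 ||
    (isTRUE(all.equal(cv$mean_accuracy, 1)) &&
       cv$selected_epoch <= overfit_epochs)
}

#' @export
print.grid_result <- function(x, ...) {
  tab <- x$table
  tab$accuracy <- ifelse(tab$overfit, "-",
                         sprintf("%.1f%% (%d)", 100 * tab$mean_accuracy,
                                 tab$epoch))
  print(tab[, c("dataset", "montage", "architecture", "optimizer",
                "learning_rate", "accuracy")], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.grid_result <- function(x, ...) x$table
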