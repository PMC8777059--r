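#' Training protocol configuration
#'
#' @param optimizer `"sgd"`, `"rmsprop"` or `"adam"`.
#' @param learning_rate positive step size (the printed grid uses 0.01,
#'   0.001, 0.0001).
#' @param batch_size minibatch size (default 10; 20 is used for the
#'   4-channel datasets).
#' @param max_epochs upper bound on training epochs.
#' @param patience early-stopping patience: training stops once the
#'   validation loss has failed to improve for this many consecutive epochs
#'   (default 2).
#' @param min_delta minimum decrease of validation loss that counts as an
#'   improvement (default 0).
#' @param early_stopping monitor validation loss and stop early
#'   (default `TRUE`; requires validation data).
#' @param standardize per-channel standardization using training-set
#'   mean/SD before model input (default `TRUE`).
#' @param seed master seed for weight initialization, batch shuffling and
#'   dropout.
#' @return A list of class `"train_control"`.
#' @export
train_control <- function(optimizer = c("sgd", "rmsprop", "adam"),
                          learning_rate = 0.001,
                          batch_size = 10L,
                          max_epochs = 100L,
                          patience = 2L,
                          min_delta = 0,
                          early_stopping = TRUE,
                          standardize = TRUE,
                          seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1 || max_epochs < 1) {
    stop("batch_size and max_epochs must be positive")
  }
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 early_stopping = isTRUE(early_stopping),
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "train_control")
}

# ---- optimizers ------------------------------------------------------------

optimizer_init <- function(weights) {
  list(t = 0L,
       m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

optimizer_step <- function(weights, grads, state, control) {
  lr <- control$learning_rate
  state$t <- state$t + 1L
  for (i in seq_along(weights)) {
    g <- grads[[i]]
    # engine returns row-vector gradients for vector-shaped biases
    if (!is.matrix(weights[[i]])) g <- as.numeric(g)
    switch(control$optimizer,
      sgd = {
        weights[[i]] <- weights[[i]] - lr * g
      },
      rmsprop = {
        state$v[[i]] <- 0.9 * state$v[[i]] + 0.1 * g^2
        weights[[i]] <- weights[[i]] - lr * g / (sqrt(state$v[[i]]) + 1e-7)
      },
      adam = {
        state$m[[i]] <- 0.9 * state$m[[i]] + 0.1 * g
        state$v[[i]] <- 0.999 * state$v[[i]] + 0.001 * g^2
        mhat <- state$m[[i]] / (1 - 0.9^state$t)
        vhat <- state$v[[i]] / (1 - 0.999^state$t)
        weights[[i]] <- weights[[i]] - lr * mhat / (sqrt(vhat) + 1e-7)
      })
  }
  list(weights = weights, state = state)
}

# ---- early stopping --------------------------------------------------------

#' Early-stopping epoch for a validation-loss sequence
#'
#' Pure form of the stopping monitor (monitor = validation loss, mode = min):
#' an epoch improves when its loss is below the best-so-far by more than
#' `min_delta`; after `patience` consecutive non-improving epochs training
#' stops at the epoch that exhausted the patience.
#'
#' @param val_losses numeric vector, one loss per epoch, in epoch order.
#' @param patience consecutive non-improving epochs tolerated (default 2).
#' @param min_delta minimum improvement (default 0).
#' @return The number of epochs actually run: the stopping epoch, or
#'   `length(val_losses)` if the sequence never triggers the rule.
#' @examples
#' early_stop_epoch(c(1.0, 0.9, 0.91, 0.92))  # 4
#' @export
early_stop_epoch <- function(val_losses, patience = 2L, min_delta = 0) {
  if (!length(val_losses)) stop("val_losses must be non-empty")
  best <- Inf
  wait <- 0L
  for (t in seq_along(val_losses)) {
    if (val_losses[t] < best - min_delta) {
      best <- val_losses[t]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(t)
    }
  }
  length(val_losses)
}

# ---- standardization -------------------------------------------------------

channel_scaler <- function(x) {
  # x: (n, T, C); statistics pooled over instances and time, per channel
  nc <- dim(x)[3]
  mu <- numeric(nc)
  sd_ <- numeric(nc)
  for (c in seq_len(nc)) {
    v <- x[, , c]
    mu[c] <- mean(v)
    sd_[c] <- stats::sd(as.numeric(v))
    if (!is.finite(sd_[c]) || sd_[c] < 1e-12) sd_[c] <- 1
  }
  list(mean = mu, sd = sd_)
}

apply_scaler <- function(x, scaler) {
  for (c in seq_len(dim(x)[3])) {
    x[, , c] <- (x[, , c] - scaler$mean[c]) / scaler$sd[c]
  }
  x
}

# ---- evaluation ------------------------------------------------------------

evaluate_instances <- function(weights, spec, x, y, chunk = 256L) {
  probs <- model_predict_probs(weights, spec, x, chunk = chunk)
  loss <- -mean(rowSums(y * log(probs + 1e-12)))
  acc <- mean(max.col(probs, ties.method = "first") ==
                max.col(y, ties.method = "first"))
  list(loss = loss, accuracy = acc, probs = probs)
}

# ---- the fitting function --------------------------------------------------

#' Fit an emotion classifier to segmented EEG instances
#'
#' The central fitting routine: trains an LSTM or Bi-LSTM on 3-second EEG
#' segments (instances of shape timesteps x channels, each inheriting its
#' trial's positive/negative label) by minibatch gradient descent on the
#' categorical cross-entropy, with optional early stopping on validation
#' loss. All randomness — weight initialization, batch shuffling, dropout —
#' derives from `control$seed`, so a repeated fit is identical.
#'
#' @param x instance array `(n, timesteps, channels)`, or a
#'   `segmented_dataset` (then all its segments become instances).
#' @param y one-hot label matrix `(n, 2)` or character labels; taken from the
#'   dataset when `x` is a `segmented_dataset`.
#' @param spec a [model_spec()]; `input_timesteps`/`input_channels` are
#'   checked against the data.
#' @param control a [train_control()].
#' @param validation optional `list(x =, y =)` held-out instances monitored
#'   each epoch (required for early stopping).
#' @param verbose print one line per epoch.
#' @return An object of class `"eeg_classifier"` with the trained weights,
#'   per-epoch `history` (loss/accuracy, and validation metrics when given),
#'   `epochs_run`, the channel `scaler`, `spec` and `control`. Methods:
#'   [predict.eeg_classifier()], `print`, `summary`, `coef`, `plot`.
#' @export
eeg_classifier <- function(x, y = NULL, spec = model_spec(),
                           control = train_control(), validation = NULL,
                           verbose = FALSE) {
  if (inherits(x, "segmented_dataset")) {
    fl <- flatten_instances(x)
    x <- fl$x
    y <- fl$y
  }
  stopifnot(length(dim(x)) == 3L)
  if (is.character(y) || is.factor(y)) y <- one_hot(as.character(y))
  stopifnot(nrow(y) == dim(x)[1])
  if (dim(x)[2] != spec$input_timesteps || dim(x)[3] != spec$input_channels) {
    stop(sprintf("data is %d timesteps x %d channels but spec wants %d x %d",
                 dim(x)[2], dim(x)[3], spec$input_timesteps,
                 spec$input_channels))
  }
  if (dim(x)[1] == 0L) stop("empty training split")
  has_val <- !is.null(validation)
  if (has_val && (is.null(validation$x) || dim(validation$x)[1] == 0L)) {
    stop("empty validation split")
  }
  if (control$early_stopping && !has_val) {
    stop("early stopping requires validation data")
  }

  scaler <- if (control$standardize) channel_scaler(x) else
    list(mean = rep(0, dim(x)[3]), sd = rep(1, dim(x)[3]))
  x <- apply_scaler(x, scaler)
  xv <- NULL
  yv <- NULL
  if (has_val) {
    xv <- apply_scaler(validation$x, scaler)
    yv <- validation$y
    if (is.character(yv) || is.factor(yv)) yv <- one_hot(as.character(yv))
  }

  model <- build_model(spec, seed = control$seed)
  weights <- unname(model$weights)
  wnames <- names(model$weights)
  opt <- optimizer_init(weights)
  bi <- spec$architecture == "bilstm"
  n <- dim(x)[1]

  hist <- list()
  best <- Inf
  wait <- 0L
  epochs_run <- 0L

  with_seed(control$seed + 1L, {
    for (epoch in seq_len(control$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0
      for (start in seq(1L, n, by = control$batch_size)) {
        idx <- ord[start:min(start + control$batch_size - 1L, n)]
        xb <- instances_to_cube(x[idx, , , drop = FALSE])
        yb <- y[idx, , drop = FALSE]
        res <- .rnn_grad(weights, xb, yb, spec$layer_units, bi,
                         spec$dropout_rate, spec$dropout_after,
                         TRUE, sample.int(.Machine$integer.max, 1L))
        stepped <- optimizer_step(weights, res$grads, opt, control)
        weights <- stepped$weights
        opt <- stepped$state
        ep_loss <- ep_loss + res$loss * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(res$probs, ties.method = "first") ==
                max.col(yb, ties.method = "first"))
      }
      row <- data.frame(epoch = epoch, loss = ep_loss / n,
                        accuracy = ep_correct / n,
                        val_loss = NA_real_, val_accuracy = NA_real_)
      if (has_val) {
        ev <- evaluate_instances(weights, spec, xv, yv)
        row$val_loss <- ev$loss
        row$val_accuracy <- ev$accuracy
      }
      hist[[epoch]] <- row
      epochs_run <- epoch
      if (verbose) {
        cat(sprintf("epoch %3d  loss %.4f  acc %.3f%s\n", epoch, row$loss,
                    row$accuracy,
                    if (has_val) sprintf("  val_loss %.4f  val_acc %.3f",
                                         row$val_loss, row$val_accuracy)
                    else ""))
      }
      if (control$early_stopping) {
        if (row$val_loss < best - control$min_delta) {
          best <- row$val_loss
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= control$patience) break
        }
      }
    }
  })

  names(weights) <- wnames
  structure(list(spec = spec, control = control, weights = weights,
                 history = do.call(rbind, hist), epochs_run = epochs_run,
                 scaler = scaler, classes = class_names(spec)),
            class = "eeg_classifier")
}

#' Train with early stopping on an explicit train/validation split
#'
#' Thin protocol wrapper around [eeg_classifier()]: fits with validation-loss
#' early stopping and reports the number of epochs actually run (the
#' per-fold `T` of the cross-validation protocol).
#'
#' @param x_train,y_train training instances and one-hot labels.
#' @param x_val,y_val validation instances and labels.
#' @param spec a [model_spec()].
#' @param control a [train_control()] (early stopping is forced on).
#' @return list with elements `fit` (the `eeg_classifier`), `history`, and
#'   `T` (epochs run).
#' @export
train_with_early_stopping <- function(x_train, y_train, x_val, y_val,
                                      spec = model_spec(),
                                      control = train_control()) {
  control$early_stopping <- TRUE
  fit <- eeg_classifier(x_train, y_train, spec = spec, control = control,
                        validation = list(x = x_val, y = y_val))
  list(fit = fit, history = fit$history, T = fit$epochs_run)
}

# ---- methods ---------------------------------------------------------------

#' Predict emotion classes for new segments
#'
#' @param object a fitted [eeg_classifier()].
#' @param newdata instance array `(n, timesteps, channels)` or a
#'   `segmented_dataset`.
#' @param type `"prob"` for class scores (rows sum to 1) or `"class"` for
#'   hard labels.
#' @param ... unused.
#' @return Matrix of scores or character vector of labels.
#' @export
predict.eeg_classifier <- function(object, newdata, type = c("prob", "class"),
                                   ...) {
  type <- match.arg(type)
  if (inherits(newdata, "segmented_dataset")) {
    newdata <- flatten_instances(newdata)$x
  }
  if (length(dim(newdata)) == 2L) {
    newdata <- array(newdata, dim = c(1L, dim(newdata)))
  }
  xs <- apply_scaler(newdata, object$scaler)
  probs <- model_predict_probs(object$weights, object$spec, xs)
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

#' @export
print.eeg_classifier <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<eeg_classifier> %s (%s/%s units), %d epoch(s) run\n",
              toupper(x$spec$architecture),
              paste(x$spec$layer_units, collapse = "/"),
              x$control$optimizer, x$epochs_run))
  cat(sprintf("  final training loss %.4f, accuracy %.3f", last$loss,
              last$accuracy))
  if (!is.na(last$val_loss)) {
    cat(sprintf("; validation loss %.4f, accuracy %.3f", last$val_loss,
                last$val_accuracy))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.eeg_classifier <- function(object, ...) {
  cat("Emotion classifier fit\n")
  print(object$spec)
  cat(sprintf("optimizer %s, learning rate %g, batch %d, seed %d\n",
              object$control$optimizer, object$control$learning_rate,
              object$control$batch_size, object$control$seed))
  cat(sprintf("epochs run: %d%s\n", object$epochs_run,
              if (object$control$early_stopping)
                " (early stopping, patience 2 on validation loss)" else ""))
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.eeg_classifier <- function(object, ...) object$weights

#' @export
plot.eeg_classifier <- function(x, ...) {
  h <- x$history
  rng <- range(c(h$loss, h$val_loss), na.rm = TRUE)
  graphics::plot(h$epoch, h$loss, type = "b", pch = 16, ylim = rng,
                 xlab = "epoch", ylab = "categorical cross-entropy",
                 main = "Training history", ...)
  if (any(!is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, type = "b", pch = 1, lty = 2)
    graphics::legend("topright", c("training", "validation"),
                     pch = c(16, 1), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
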