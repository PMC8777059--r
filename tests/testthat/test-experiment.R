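test_that("fold sizes for 195 trials are 49/49/49/48, disjoint, exhaustive", {
  f <- make_folds(195L, k = 4L, seed = 1L)
  sizes <- tabulate(f$fold, 4L)
  expect_equal(sort(sizes, decreasing = TRUE), c(49L, 49L, 49L, 48L))
  expect_equal(sort(unlist(lapply(1:4, function(i) which(f$fold == i)))),
               1:195)
  # three of the four rotations validate on 49 and train on 146
  expect_equal(sum(195L - sizes == 146L), 3L)
})

test_that("fold partition properties hold for random sizes", {
  set.seed(70)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    k <- sample(2:min(n, 6), 1)
    f <- make_folds(n, k = k, seed = rep)
    sizes <- tabulate(f$fold, k)
    expect_lte(diff(range(sizes)), 1L)
    expect_equal(sum(sizes), n)
  }
  expect_equal(sort(tabulate(make_folds(4L, 4L, 1L)$fold, 4L)),
               rep(1L, 4))
  expect_error(make_folds(3L, k = 4L), "at least")
})

test_that("early stopping follows the patience-2 rule on a forced sequence", {
  # improvement, then two consecutive non-improving epochs -> stop at 4
  expect_equal(early_stop_epoch(c(1.0, 0.9, 0.91, 0.92)), 4L)
  # monotone decrease never stops
  expect_equal(early_stop_epoch(seq(1, 0.1, by = -0.1)), 10L)
  # plateau from the start: epochs 2 and 3 exhaust patience
  expect_equal(early_stop_epoch(c(1, 1, 1, 1)), 3L)
  # min_delta makes tiny improvements count as none
  expect_equal(early_stop_epoch(c(1.0, 0.999, 0.998), patience = 2L,
                                min_delta = 0.01), 3L)
  expect_error(early_stop_epoch(numeric(0)), "non-empty")
})

test_that("the training loop stops exactly where the pure rule says", {
  toy <- toy_instances(n = 16L, timesteps = 12L, channels = 2L, shift = 0)
  sp <- model_spec("lstm", layer_units = 3L, dropout_after = integer(0),
                   input_timesteps = 12L, input_channels = 2L)
  ctl <- train_control("sgd", learning_rate = 0.05, batch_size = 8L,
                       max_epochs = 12L, seed = 4L)
  fit <- eeg_classifier(toy$x, toy$y, spec = sp, control = ctl,
                        validation = list(x = toy$x, y = toy$y))
  expect_equal(fit$epochs_run,
               early_stop_epoch(fit$history$val_loss, patience = 2L))
  expect_lte(fit$epochs_run, 12L)
})

test_that("select_epoch returns the max early-stopping epoch", {
  expect_equal(select_epoch(c(10, 12, 9, 11)), 12)
  expect_equal(select_epoch(c(30, 30, 30, 30)), 30)
  expect_equal(select_epoch(7), 7)
  expect_error(select_epoch(integer(0)), "non-empty")
})

test_that("trial majority vote aggregates segments with positive tie-break", {
  pred <- c(rep("positive", 11), rep("negative", 9),   # 11 vs 9
            rep("positive", 10), rep("negative", 10),  # tie
            rep("negative", 20))                       # unanimous
  ids <- rep(c("t1", "t2", "t3"), each = 20)
  mv <- trial_majority_vote(pred, ids,
                            truth = c(t1 = "positive", t2 = "negative",
                                      t3 = "negative"))
  expect_equal(unname(mv$predicted), c("positive", "positive", "negative"))
  expect_equal(mv$accuracy, 2 / 3)
  expect_error(trial_majority_vote(pred[-c(1, 21)], ids[-c(1, 21)]),
               "unequal")
})

test_that("cross-validation protocol: no leakage, exact arithmetic, determinism", {
  # small but real run through the full two-phase protocol
  cfg <- tiny_config(n_subjects = 2L, n_trials_per_subject = 6L,
                     stratify = c(positive = 6L, negative = 6L,
                                  excluded = 0L),
                     duration = 12, seed = 16L, effect_size = 2)
  ds <- assemble_dataset(preprocess_cohort(generate_cohort(cfg)),
                         segment_s = 3, n_segments = 4)
  sp <- model_spec("lstm", layer_units = 4L, dropout_after = integer(0),
                   input_timesteps = 750L, input_channels = 8L)
  ctl <- train_control("adam", learning_rate = 0.005, batch_size = 12L,
                       max_epochs = 3L, seed = 5L)
  cv <- run_cv(ds, spec = sp, control = ctl, k = 4L)
  expect_length(cv$T, 4L)
  expect_equal(cv$selected_epoch, max(cv$T))
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies))
  expect_equal(tabulate(cv$folds$fold, 4L), rep(3L, 4L))

  # identical master seed reproduces the result exactly
  cv2 <- run_cv(ds, spec = sp, control = ctl, k = 4L)
  cv$histories <- cv2$histories <- NULL
  expect_equal(cv, cv2)
})

test_that("run_cv rejects degenerate datasets", {
  cfg <- tiny_config(n_subjects = 1L, n_trials_per_subject = 4L,
                     stratify = c(positive = 4L, negative = 0L,
                                  excluded = 0L),
                     duration = 12, seed = 17L)
  ds <- assemble_dataset(generate_cohort(cfg), segment_s = 3, n_segments = 4)
  expect_error(run_cv(ds), "both classes")
})

test_that("grid runs one cell per optimizer x rate and flags bad cells", {
  cfg <- tiny_config(n_subjects = 2L, n_trials_per_subject = 4L,
                     stratify = c(positive = 4L, negative = 4L,
                                  excluded = 0L),
                     duration = 6, seed = 18L, effect_size = 2)
  ds <- assemble_dataset(preprocess_cohort(generate_cohort(cfg)),
                         segment_s = 3, n_segments = 2)
  sp <- model_spec("lstm", layer_units = 3L, dropout_after = integer(0),
                   input_timesteps = 750L, input_channels = 8L)
  ctl <- train_control(batch_size = 8L, max_epochs = 2L, seed = 6L)
  gr <- run_grid(ds, spec = sp, optimizers = c("sgd", "adam"),
                 learning_rates = c(0.01, 0.001), control = ctl, k = 2L)
  tab <- as.data.frame(gr)
  expect_equal(nrow(tab), 4L)
  expect_equal(sort(unique(tab$optimizer)), c("adam", "sgd"))
  # flagged rows carry no accuracy
  expect_true(all(is.na(tab$mean_accuracy[tab$overfit])))
  expect_true(all(!is.na(tab$mean_accuracy[!tab$overfit])))
})

test_that("overfit flag fires on high validation loss or instant perfection", {
  fake_cv <- function(loss, acc, epoch) {
    structure(list(final_val_loss = loss, mean_accuracy = acc,
                   selected_epoch = epoch,
                   histories = list(phase1 = list())),
              class = "cv_result")
  }
  expect_true(rteeg:::overfit_flag(fake_cv(c(1.4, 1.2), 0.9, 20)))
  expect_true(rteeg:::overfit_flag(fake_cv(c(0.2, 0.3), 1.0, 3)))
  expect_false(rteeg:::overfit_flag(fake_cv(c(0.2, 0.3), 1.0, 30)))
  expect_false(rteeg:::overfit_flag(fake_cv(c(0.4, 0.5), 0.9, 10)))
})
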