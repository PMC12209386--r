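#' Run a full seeded classification experiment
#'
#' Executes the whole pipeline in order: simulate (or accept) labelled
#' recordings, verify the subclinical gate, featurize, hold out a balanced
#' test set, build the stratified 5-fold plan, train one classifier per
#' rotation (with time-slice oversampling of minority training classes),
#' and evaluate the fold-ensemble on the held-out test set.
#'
#' @param task `"pd-vs-et"` (two-class) or `"three-class"`.
#' @param n_per_class recordings per class; a single number is recycled
#'   over the task's classes. Ignored when `recordings` are supplied or
#'   `preset = "paper"`.
#' @param preset simulator preset passed to [simulate_dataset()].
#' @param n_test_per_class held-out test recordings per class (default 10).
#' @param k folds.
#' @param seed master seed for simulation, splitting, folds, augmentation
#'   and training.
#' @param config a [sim_config()].
#' @param pconfig a [preprocess_config()].
#' @param fconfig a [spectrogram_config()].
#' @param recordings optional pre-built list of [tremor_recording()]s
#'   (skips simulation).
#' @param baseline also train and evaluate the convolutional-LSTM reference
#'   architecture on the preprocessed displacement channels.
#' @param ... model settings passed to [tremor_lstm()] via [train_cv()]
#'   (e.g. `hidden`, `fc`, `dropout`, `l2`, `batch_size`, `max_epochs`).
#' @return An object of class `tremor_experiment`: `fold_table` (training /
#'   validation / per-fold test accuracy in the 5-fold layout), `report`
#'   (test [evaluation_report()]), `cv`, the test split, and optionally
#'   `baseline_report`.
#' @export
run_experiment <- function(task = c("pd-vs-et", "three-class"),
                           n_per_class = 30, preset = "separable",
                           n_test_per_class = 10, k = 5, seed = 1,
                           config = sim_config(),
                           pconfig = preprocess_config(),
                           fconfig = spectrogram_config(),
                           recordings = NULL, baseline = FALSE, ...) {
  task <- match.arg(task)
  classes <- if (task == "pd-vs-et") c("PD", "ET") else c("normal", "PD", "ET")
  if (is.null(recordings)) {
    counts <- if (identical(preset, "paper")) NULL
              else stats::setNames(rep_len(n_per_class, length(classes)), classes)
    recordings <- if (identical(preset, "paper"))
      simulate_dataset(preset = "paper", config = config, seed = seed)
    else simulate_dataset(counts, preset = preset, config = config, seed = seed)
  }
  recordings <- Filter(function(r) class_name(r$label) %in% classes, recordings)
  stopifnot(all(vapply(recordings, function(r) is_subclinical(r$rating), logical(1))))

  fd <- featurize_dataset(recordings, pconfig, fconfig)
  split <- holdout_split(fd, n_test_per_class = n_test_per_class, seed = seed)
  plan <- make_folds(split$trainval, k = k, seed = seed)
  cv <- train_cv(split$trainval, plan, seed = seed, ...)

  test_labels <- split$test$meta$label
  fold_test_acc <- vapply(cv$fits, function(fit) {
    mean(predict(fit, split$test) == test_labels)
  }, numeric(1))
  fold_table <- data.frame(fold = seq_len(k),
                           training = cv$train_acc,
                           validation = cv$val_acc,
                           testing = fold_test_acc)
  probs <- predict(cv, split$test, type = "prob")
  codes <- vapply(classes, class_code, integer(1))
  report <- evaluation_report(test_labels, probs[, match(sort(codes), codes), drop = FALSE],
                              classes = sort(codes))

  out <- list(task = task, seed = seed, fold_table = fold_table,
              mean_test_accuracy = mean(fold_test_acc),
              report = report, cv = cv, split = split, plan = plan)

  if (baseline) {
    out$baseline_report <- .run_baseline(recordings, split, pconfig, seed)
  }
  structure(out, class = "tremor_experiment")
}

# Baseline path: the conv-LSTM consumes the three preprocessed scalar
# displacement series as channels; one fold of the trainval pool drives
# early stopping.
.run_baseline <- function(recordings, split, pconfig, seed) {
  chans <- lapply(recordings, function(r) do.call(cbind, preprocess_recording(r, pconfig)))
  names(chans) <- vapply(recordings, `[[`, character(1), "id")
  labs <- stats::setNames(vapply(recordings, `[[`, integer(1), "label"), names(chans))
  tv <- split$trainval$meta$id; te <- split$test$meta$id
  plan1 <- make_folds(split$trainval, k = 5, seed = seed)
  val_ids <- plan1$folds[[1]]
  tr_ids <- setdiff(tv, val_ids)
  model <- build_baseline_convlstm(input_shape = dim(chans[[1]]),
                                   n_classes = length(unique(labs)), seed = seed)
  model <- train_convlstm(model, chans[tr_ids], labs[tr_ids],
                          validation = list(x = chans[val_ids], y = labs[val_ids]),
                          max_epochs = 30, patience = 5, seed = seed)
  probs <- predict(model, chans[te], type = "prob")
  evaluation_report(labs[te], probs, classes = sort(unique(labs)))
}

#' @export
print.tremor_experiment <- function(x, ...) {
  cat(sprintf("<tremor_experiment> task %s, seed %s\n", x$task, x$seed))
  ft <- x$fold_table
  tab <- t(as.matrix(ft[, c("training", "validation", "testing")]))
  colnames(tab) <- paste0("fold", ft$fold)
  print(round(cbind(tab, mean = rowMeans(tab)), 3))
  cat(sprintf("mean test accuracy over folds: %.3f; ensemble accuracy: %.3f\n",
              x$mean_test_accuracy, x$report$accuracy))
  print(x$report)
  invisible(x)
}
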