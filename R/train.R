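#' Fit the LSTM tremor classifier
#'
#' Trains the sequence classifier (input normalization layer -> LSTM ->
#' summed hidden aggregate -> ReLU -> fully connected stack -> softmax) by
#' minimising categorical cross-entropy with mini-batch Adam (or SGD),
#' L2 weight decay, dropout, and early stopping on validation accuracy:
#' training stops once the validation accuracy has failed to improve for
#' `patience` consecutive checks and the best-validation weights are
#' restored.
#'
#' @param x list of feature sequences (equal-shape frames x features
#'   matrices, e.g. from [featurize_recording()]), or a [feature_dataset()]
#'   (in which case `y` is taken from its metadata).
#' @param y class labels (integer codes 0/1/2 or names), one per sequence.
#' @param hidden LSTM hidden units (search range 10-300, step 10).
#' @param fc widths of the fully connected hidden layers (0-2 inner widths
#'   plus the implicit output layer; 1-3 FC layers total, widths 10-300).
#' @param dropout dropout probability on the head activations.
#' @param l2 L2 regularization factor (weight decay).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param lr learning rate.
#' @param batch_size mini-batch size (16-128; 32 is the tuned default).
#' @param max_epochs epoch budget.
#' @param patience early-stopping patience in validation checks (one check
#'   per epoch).
#' @param validation either a fraction of `x` to set aside (stratified), or
#'   a list `list(x = , y = )` of held-out sequences; `NULL` disables early
#'   stopping.
#' @param seed integer seed governing initialisation, batching and dropout;
#'   fixed seed gives bitwise-identical training histories.
#' @param verbose print per-epoch progress.
#' @return An object of class `tremor_lstm` with components `params`,
#'   `norm`, `classes`, `history` (per-epoch loss/accuracy), `best_epoch`
#'   and the call configuration. Supports `print()`, `summary()`,
#'   `predict()`, `plot()` and `coef()`.
#' @export
tremor_lstm <- function(x, y = NULL, hidden = 50, fc = 50, dropout = 0.1,
                        l2 = 1e-4, optimizer = c("adam", "sgd"), lr = 3e-3,
                        batch_size = 32, max_epochs = 150, patience = 10,
                        validation = 0.2, seed = 1, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  if (inherits(x, "feature_dataset")) {
    y <- x$meta$label
    x <- x$sequences
  }
  if (is.null(y) || length(y) != length(x)) stop("need one label per sequence")
  y <- vapply(y, class_code, integer(1))
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least two classes to fit a classifier")
  y_idx <- match(y, classes)
  D <- ncol(x[[1]])

  with_seed(seed, {
    # carve out a stratified validation split if requested
    val_x <- list(); val_y <- integer(0)
    if (is.list(validation) && !is.null(validation$x)) {
      val_x <- validation$x
      val_y <- match(vapply(validation$y, class_code, integer(1)), classes)
      if (anyNA(val_y)) stop("validation labels outside the training classes")
    } else if (is.numeric(validation) && validation > 0) {
      hold <- unlist(lapply(split(seq_along(y_idx), y_idx), function(i)
        sample(i, max(1L, round(validation * length(i))))), use.names = FALSE)
      val_x <- x[hold]; val_y <- y_idx[hold]
      x <- x[-hold]; y_idx <- y_idx[-hold]
    }

    # input-normalization layer: feature-wise statistics of the training set
    all_feat <- do.call(rbind, x)
    norm <- list(mu = colMeans(all_feat),
                 sd = pmax(apply(all_feat, 2L, stats::sd), 1e-8))

    cell <- lstm_params(D, hidden)
    params <- list(lstm = list(U = cell$U, W = cell$W, b = cell$b),
                   head = .init_head(hidden, fc, length(classes)))
    model <- .lstm_model_interface(params, norm, dropout, hidden)
    config <- list(n_classes = length(classes), batch_size = batch_size,
                   optimizer = optimizer, lr = lr, l2 = l2,
                   max_epochs = max_epochs, patience = patience)
    fit <- .nn_train_loop(model, x, y_idx, val_x, val_y, config)
  })

  structure(list(params = fit$params, norm = norm, hidden = hidden,
                 dropout = dropout, classes = classes,
                 history = fit$history, best_epoch = fit$best_epoch,
                 config = c(config, list(fc = fc, seed = seed)),
                 input_dim = D),
            class = "tremor_lstm")
}

#' Predict from a fitted tremor classifier
#'
#' @param object a [tremor_lstm()] fit.
#' @param newdata list of feature sequences or a [feature_dataset()].
#' @param type `"class"` for hard labels (integer class codes) or `"prob"`
#'   for the softmax probability matrix (columns named by class).
#' @param ... unused.
#' @return Integer labels or a probability matrix with rows summing to 1.
#' @export
predict.tremor_lstm <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_dataset")) newdata <- newdata$sequences
  if (ncol(newdata[[1]]) != object$input_dim)
    stop("feature width does not match the fitted model")
  model <- .lstm_model_interface(object$params, object$norm, 0, object$hidden)
  probs <- .softmax(model$forward(object$params, newdata, train = FALSE)$logits)
  colnames(probs) <- class_name(object$classes)
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

#' @export
print.tremor_lstm <- function(x, ...) {
  cat(sprintf("<tremor_lstm> %d-class LSTM: %d features -> %d hidden -> head (%s)\n",
              length(x$classes), x$input_dim, x$hidden,
              paste(c(x$config$fc, length(x$classes)), collapse = " -> ")))
  h <- x$history
  cat(sprintf("  trained %d epochs (best at %d): loss %.4f, train acc %.3f, val acc %s\n",
              nrow(h), x$best_epoch, h$loss[nrow(h)], h$train_acc[nrow(h)],
              if (is.na(h$val_acc[nrow(h)])) "-" else sprintf("%.3f", max(h$val_acc, na.rm = TRUE))))
  invisible(x)
}

#' @export
summary.tremor_lstm <- function(object, ...) {
  n_par <- sum(unlist(.map_params(length, object$params)))
  cat(sprintf("LSTM tremor classifier (%s)\n",
              paste(class_name(object$classes), collapse = " vs ")))
  cat(sprintf("  parameters: %d; dropout %.3g; L2 %.3g; optimizer %s; batch %d\n",
              n_par, object$dropout, object$config$l2, object$config$optimizer,
              object$config$batch_size))
  cat(sprintf("  epochs run: %d (early-stopped best epoch %d)\n",
              nrow(object$history), object$best_epoch))
  print(utils::tail(object$history, 3L), row.names = FALSE)
  invisible(object)
}

#' @export
coef.tremor_lstm <- function(object, ...) object$params

#' Plot training history
#' @param x a [tremor_lstm()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tremor_lstm <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "accuracy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("bottomright", c("training", "validation"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Cross-validated training over a fold plan
#'
#' For every rotation of the fold plan: the rotation's training recordings
#' are balanced by time-slice oversampling, a classifier is fitted with the
#' rotation's validation fold driving early stopping, and the fold's
#' validation accuracy is recorded.
#'
#' @param trainval a [feature_dataset()] (no augmented entries).
#' @param plan a [make_folds()] plan over `trainval`.
#' @param aug_config an [augmentation_config()].
#' @param seed integer master seed; each fold derives its own sub-seed.
#' @param ... passed on to [tremor_lstm()].
#' @return An object of class `tremor_cv`: list of per-fold `fits`,
#'   `val_acc`, `train_acc` and the plan.
#' @export
train_cv <- function(trainval, plan, aug_config = augmentation_config(),
                     seed = 1, ...) {
  fits <- vector("list", plan$k)
  val_acc <- train_acc <- numeric(plan$k)
  for (f in seq_len(plan$k)) {
    val_ids <- plan$folds[[f]]
    train_ids <- setdiff(trainval$meta$id, val_ids)
    rot <- oversample_balance(dataset_subset(trainval, train_ids),
                              aug_config, seed = seed * 1000L + f)
    val <- dataset_subset(trainval, val_ids)
    fit <- tremor_lstm(rot$sequences, rot$meta$label,
                       validation = list(x = val$sequences, y = val$meta$label),
                       seed = seed * 100L + f, ...)
    fits[[f]] <- fit
    val_acc[f] <- max(fit$history$val_acc, na.rm = TRUE)
    train_acc[f] <- fit$history$train_acc[fit$best_epoch]
  }
  structure(list(fits = fits, val_acc = val_acc, train_acc = train_acc,
                 plan = plan), class = "tremor_cv")
}

#' @export
print.tremor_cv <- function(x, ...) {
  cat(sprintf("<tremor_cv> %d folds; validation accuracy %s (mean %.3f)\n",
              length(x$fits), paste(sprintf("%.3f", x$val_acc), collapse = ", "),
              mean(x$val_acc)))
  invisible(x)
}

#' Ensemble prediction from cross-validated fits
#'
#' Averages the softmax probabilities of the per-fold models.
#'
#' @param object a [train_cv()] result.
#' @param newdata list of sequences or [feature_dataset()].
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @export
predict.tremor_cv <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  probs <- Reduce(`+`, lapply(object$fits, predict, newdata = newdata,
                              type = "prob")) / length(object$fits)
  if (type == "prob") return(probs)
  object$fits[[1]]$classes[max.col(probs, ties.method = "first")]
}
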