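#' Confusion matrices, scalar metrics and ROC/AUC
#'
#' Evaluation follows the one-vs-all protocol for the three-class problem:
#' each class in turn is treated as positive and the 3 x 3 confusion matrix
#' is collapsed to 2 x 2 before the binary metrics are computed. Ratios
#' with a zero denominator are reported as `NaN` (flagged), never silently
#' as zero.
#'
#' @name evaluation
NULL

#' Confusion matrix
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes class labels defining row/column order (rows are the true
#'   class, columns the predicted class).
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, classes = sort(unique(c(y_true, y_pred)))) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (!all(c(y_true, y_pred) %in% classes)) stop("labels outside the declared classes")
  cm <- table(factor(y_true, levels = classes), factor(y_pred, levels = classes))
  cm <- unclass(as.matrix(cm))
  dimnames(cm) <- list(true = as.character(classes), predicted = as.character(classes))
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d samples, %d correct\n", sum(x), sum(diag(x))))
  print(unclass(x))
  invisible(x)
}

.safe_ratio <- function(num, den) if (den == 0) NaN else num / den

#' Binary metrics from a confusion matrix
#'
#' Computes the full scalar metric suite for a designated positive class:
#' accuracy, sensitivity (recall/TPR), precision (PPV), specificity (TNR),
#' F1 (harmonic mean of precision and sensitivity), FPR, and NPV. Any
#' metric with a zero denominator is `NaN` and listed in the `undefined`
#' attribute.
#'
#' @param cm a 2 x 2 [confusion()] matrix, or an n x n matrix together with
#'   `positive` naming the one-vs-all positive class.
#' @param positive the positive class (row/column name); defaults to the
#'   first class of a 2 x 2 matrix.
#' @return A named list of class `metric_set`.
#' @export
binary_metrics <- function(cm, positive = rownames(cm)[1]) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  positive <- as.character(positive)
  if (!positive %in% rownames(cm)) stop("positive class not in the matrix")
  pos <- rownames(cm) == positive
  tp <- sum(cm[pos, pos]); fn <- sum(cm[pos, !pos])
  fp <- sum(cm[!pos, pos]); tn <- sum(cm[!pos, !pos])
  prec <- .safe_ratio(tp, tp + fp)
  sens <- .safe_ratio(tp, tp + fn)
  f1 <- if (is.nan(prec) || is.nan(sens) || prec + sens == 0) NaN
        else 2 * prec * sens / (prec + sens)
  out <- list(accuracy = (tp + tn) / sum(cm),
              sensitivity = sens,
              precision = prec,
              specificity = .safe_ratio(tn, tn + fp),
              f1 = f1,
              fpr = .safe_ratio(fp, fp + tn),
              npv = .safe_ratio(tn, tn + fn))
  structure(out, positive = positive,
            counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
            undefined = names(out)[vapply(out, is.nan, logical(1))],
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 3, ...) {
  cat(sprintf("<metric_set> positive class: %s\n", attr(x, "positive")))
  v <- round(unlist(x), digits)
  print(v)
  und <- attr(x, "undefined")
  if (length(und)) cat("undefined (zero denominator):", paste(und, collapse = ", "), "\n")
  invisible(x)
}

#' One-vs-all metrics for a multi-class confusion matrix
#'
#' @param cm an n x n [confusion()] matrix (n >= 2).
#' @return Named list of [binary_metrics()] `metric_set`s, one per class
#'   treated as positive.
#' @export
one_vs_all_metrics <- function(cm) {
  stats::setNames(lapply(rownames(cm), function(cl) binary_metrics(cm, cl)),
                  rownames(cm))
}

#' ROC curve and AUC from scores
#'
#' Sweeps the threshold over the unique scores (ties move the operating
#' point simultaneously), giving a curve from (0,0) to (1,1); the AUC is
#' the trapezoidal integral, which equals the Mann-Whitney probability that
#' a random positive outscores a random negative (ties counted half).
#'
#' @param scores positive-class scores (e.g. softmax probabilities).
#' @param labels binary labels; `positive` identifies the positive class.
#' @param positive the positive label value.
#' @return An object of class `roc_curve`: list with `fpr`, `tpr`,
#'   `thresholds` and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = max(labels)) {
  is_pos <- labels == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) stop("ROC needs at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- is_pos[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tied block
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[last]), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.3f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Plot an ROC curve
#' @param x a [roc_auc()] curve.
#' @param ... passed to [graphics::plot()].
#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "false positive rate",
                 ylab = "true positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Full evaluation report
#'
#' Bundles the confusion matrix, per-class one-vs-all metrics and ROC
#' curves (from class-probability scores) into one auditable object; every
#' scalar metric is recomputable from the embedded matrix.
#'
#' @param y_true true labels.
#' @param probs class-probability matrix, columns named by class.
#' @param classes class codes in column order.
#' @return List of class `eval_report` with `confusion`, `metrics` (per
#'   positive class), `roc` (per positive class) and `accuracy`.
#' @export
evaluation_report <- function(y_true, probs, classes = sort(unique(y_true))) {
  y_pred <- classes[max.col(probs, ties.method = "first")]
  cm <- confusion(y_true, y_pred, classes)
  mets <- one_vs_all_metrics(cm)
  roc <- stats::setNames(lapply(seq_along(classes), function(j)
    roc_auc(probs[, j], as.integer(y_true == classes[j]), positive = 1L)),
    as.character(classes))
  structure(list(confusion = cm, metrics = mets, roc = roc,
                 accuracy = sum(diag(cm)) / sum(cm)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f\n", x$accuracy))
  print(x$confusion)
  for (cl in names(x$metrics)) {
    m <- x$metrics[[cl]]
    cat(sprintf("  class %s (%s): sens %.3f prec %.3f spec %.3f F1 %.3f FPR %.3f NPV %.3f AUC %.3f\n",
                cl, class_name(suppressWarnings(as.integer(cl))),
                m$sensitivity, m$precision, m$specificity, m$f1, m$fpr, m$npv,
                x$roc[[cl]]$auc))
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report an [evaluation_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  out <- list(accuracy = report$accuracy,
              confusion = unclass(report$confusion),
              metrics = lapply(report$metrics, function(m) unclass(m)[]),
              auc = lapply(report$roc, `[[`, "auc"),
              roc = lapply(report$roc, function(r) list(fpr = r$fpr, tpr = r$tpr)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
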