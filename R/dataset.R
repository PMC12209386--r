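#' Feature datasets and seeded sampling utilities
#'
#' A `feature_dataset` holds the featurized recordings of a study: a `meta`
#' table (recording id, subject id, class label, augmentation provenance)
#' plus the named list of feature sequences. All splitting, fold and
#' augmentation operations are seeded and reproducible.
#'
#' @name dataset
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded package operations never
#' perturb the caller's RNG stream. With `seed = NULL` the expression runs
#' on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a feature dataset from recordings
#'
#' @param recordings list of [tremor_recording()] objects.
#' @param pconfig a [preprocess_config()].
#' @param fconfig a [spectrogram_config()].
#' @return An object of class `feature_dataset` with elements `meta`
#'   (data.frame: `id`, `subject`, `label`, `augmented`, `source`) and
#'   `sequences` (named list of `feature_seq`).
#' @export
featurize_dataset <- function(recordings, pconfig = preprocess_config(),
                              fconfig = spectrogram_config()) {
  seqs <- lapply(recordings, featurize_recording, pconfig = pconfig, fconfig = fconfig)
  ids <- vapply(recordings, `[[`, character(1), "id")
  names(seqs) <- ids
  meta <- data.frame(id = ids,
                     subject = vapply(recordings, `[[`, character(1), "subject"),
                     label = vapply(recordings, `[[`, integer(1), "label"),
                     augmented = FALSE, source = ids,
                     stringsAsFactors = FALSE)
  feature_dataset(meta, seqs)
}

#' @rdname featurize_dataset
#' @param meta metadata data.frame as described above.
#' @param sequences named list of feature sequences, names matching `meta$id`.
#' @export
feature_dataset <- function(meta, sequences) {
  if (!all(meta$id %in% names(sequences))) stop("every meta id needs a sequence")
  structure(list(meta = meta, sequences = sequences[meta$id]),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  tab <- table(factor(class_name(x$meta$label), levels = names(CLASS_LEVELS)))
  cat(sprintf("<feature_dataset> %d sequences (%s)%s\n", nrow(x$meta),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              if (any(x$meta$augmented)) sprintf(", %d augmented", sum(x$meta$augmented)) else ""))
  invisible(x)
}

#' Subset a feature dataset by recording id
#' @param dataset a [feature_dataset()].
#' @param ids recording ids to keep (order preserved).
#' @return A `feature_dataset`.
#' @export
dataset_subset <- function(dataset, ids) {
  stopifnot(all(ids %in% dataset$meta$id))
  meta <- dataset$meta[match(ids, dataset$meta$id), , drop = FALSE]
  rownames(meta) <- NULL
  feature_dataset(meta, dataset$sequences[ids])
}

#' Held-out test split with per-class quotas
#'
#' Draws exactly `n_test_per_class` recordings per class for the test set
#' (seeded); everything else is the train/validation pool. With subject
#' grouping (the default) no subject contributes recordings to both sides.
#' Augmented sequences are never eligible for testing.
#'
#' @param dataset a [feature_dataset()] of original (non-augmented)
#'   sequences.
#' @param n_test_per_class recordings per class to hold out (default 10).
#' @param seed integer seed.
#' @param group_by_subject keep each subject entirely on one side.
#' @return List with `trainval` and `test` feature datasets.
#' @export
holdout_split <- function(dataset, n_test_per_class = 10, seed = 1,
                          group_by_subject = TRUE) {
  meta <- dataset$meta[!dataset$meta$augmented, , drop = FALSE]
  test_ids <- with_seed(seed, {
    unlist(lapply(split(meta, meta$label), function(m) {
      if (nrow(m) <= n_test_per_class)
        stop(sprintf("class %s has only %d recordings; cannot hold out %d",
                     class_name(m$label[1]), nrow(m), n_test_per_class))
      if (!group_by_subject) return(sample(m$id, n_test_per_class))
      subj <- split(m$id, m$subject)[sample(length(unique(m$subject)))]
      chosen <- character(0)
      for (ids in subj) {
        if (length(chosen) + length(ids) <= n_test_per_class)
          chosen <- c(chosen, ids)
        if (length(chosen) == n_test_per_class) break
      }
      if (length(chosen) < n_test_per_class) {
        # only multi-recording subjects left: admit one and evict singletons
        extra <- subj[!vapply(subj, function(i) any(i %in% chosen), logical(1))]
        extra <- extra[lengths(extra) > 0][1]
        chosen <- c(chosen, extra[[1]])
        singles <- chosen[!chosen %in% extra[[1]]]
        chosen <- c(extra[[1]], utils::head(singles, n_test_per_class - length(extra[[1]])))
      }
      chosen
    }), use.names = FALSE)
  })
  list(trainval = dataset_subset(dataset, setdiff(dataset$meta$id, test_ids)),
       test = dataset_subset(dataset, test_ids))
}

#' Stratified k-fold plan
#'
#' Partitions the train/validation pool into `k` folds per class, so each
#' fold's class proportions are within one recording of the global ones and
#' every recording validates exactly once across the rotations.
#'
#' @param trainval a [feature_dataset()].
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return An object of class `fold_plan`: list with `folds` (list of `k`
#'   validation-id vectors), `k`, `seed`.
#' @export
make_folds <- function(trainval, k = 5, seed = 1) {
  meta <- trainval$meta
  counts <- table(meta$label)
  if (any(counts < k))
    stop("every class needs at least k recordings for k-fold validation")
  folds <- replicate(k, character(0), simplify = FALSE)
  with_seed(seed, {
    for (m in split(meta, meta$label)) {
      ids <- sample(m$id)
      assign_to <- rep(seq_len(k), length.out = length(ids))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], ids[assign_to == f])
    }
  })
  structure(list(folds = folds, k = k, seed = seed), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k=%d (validation sizes: %s), seed=%s\n", x$k,
              paste(lengths(x$folds), collapse = ", "), x$seed))
  invisible(x)
}

#' Time-slice augmentation configuration
#'
#' @param frac_range slice length as a fraction of the frame count,
#'   `c(min, max)` within (0, 1].
#' @param pad_value value used outside the slice (default 0).
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(frac_range = c(0.5, 1.0), pad_value = 0) {
  if (!(frac_range[1] <= frac_range[2] && frac_range[1] > 0 && frac_range[2] <= 1))
    stop("frac_range must satisfy 0 < min <= max <= 1")
  structure(list(frac_range = frac_range, pad_value = pad_value),
            class = "augmentation_config")
}

#' Randomized overlapping time slice of a feature sequence
#'
#' Extracts a contiguous block of frames of seeded-random length (uniform
#' over the configured fraction range) and seeded-random start, and places
#' it at a seeded-random offset inside an all-`pad_value` sequence of the
#' original length, varying the apparent start time of the tremor segment.
#' The label and column provenance are preserved.
#'
#' @param seq a `feature_seq` (frames x features), at least 2 frames.
#' @param config an [augmentation_config()].
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return A `feature_seq` of identical shape.
#' @export
time_slice <- function(seq, config = augmentation_config(), seed = NULL) {
  n <- nrow(seq)
  if (is.null(n) || n < 2L) stop("need at least 2 frames to slice")
  with_seed(seed, {
    len <- max(1L, round(stats::runif(1, config$frac_range[1], config$frac_range[2]) * n))
    start <- sample.int(n - len + 1L, 1L)
    offset <- sample.int(n - len + 1L, 1L) - 1L
    out <- matrix(config$pad_value, n, ncol(seq))
    out[offset + seq_len(len), ] <- seq[start + seq_len(len) - 1L, , drop = FALSE]
    attributes(out) <- attributes(seq)
    out
  })
}

#' Oversample minority classes to a balanced training set
#'
#' Augments every minority class with time-sliced copies of seeded-randomly
#' chosen originals until each class matches the majority count. Originals
#' are kept untouched; augmented entries carry `augmented = TRUE` and their
#' `source` id, so provenance (and test-set hygiene) stays auditable.
#'
#' @param training a [feature_dataset()] (one training rotation).
#' @param config an [augmentation_config()].
#' @param seed integer seed.
#' @return A balanced `feature_dataset`.
#' @export
oversample_balance <- function(training, config = augmentation_config(), seed = 1) {
  meta <- training$meta
  counts <- table(meta$label)
  if (length(counts) < 2L) stop("oversampling needs at least two classes")
  target <- max(counts)
  if (all(counts == target)) return(training)
  with_seed(seed, {
    add_meta <- list(); add_seq <- list()
    for (lab in names(counts)) {
      deficit <- target - counts[[lab]]
      if (deficit == 0L) next
      pool <- meta$id[meta$label == as.integer(lab)]
      picks <- sample(pool, deficit, replace = TRUE)
      for (j in seq_along(picks)) {
        src <- picks[j]
        new_id <- sprintf("%s_aug%d", src, j)
        add_seq[[new_id]] <- time_slice(training$sequences[[src]], config)
        add_meta[[new_id]] <- data.frame(
          id = new_id, subject = meta$subject[meta$id == src],
          label = as.integer(lab), augmented = TRUE, source = src,
          stringsAsFactors = FALSE)
      }
    }
    feature_dataset(rbind(meta, do.call(rbind, add_meta)),
                    c(training$sequences, add_seq))
  })
}
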