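test_that("holdout reproduces the study's train/validation fractions", {
  # PD vs ET: 83 + 30 readings, 10 per class held out -> 93/113 = 82.3%
  fd2 <- make_toy_dataset(c(PD = 83, ET = 30), seed = 1)
  sp2 <- holdout_split(fd2, n_test_per_class = 10, seed = 5)
  expect_equal(nrow(sp2$test$meta), 20L)
  expect_equal(table(sp2$test$meta$label), table(rep(c(1, 2), each = 10)),
               ignore_attr = TRUE)
  frac2 <- nrow(sp2$trainval$meta) / nrow(fd2$meta)
  expect_equal(frac2, 93 / 113)
  expect_equal(round(100 * frac2), 82)

  # three classes 122/83/30 -> 205/235 = 87.2%
  fd3 <- make_toy_dataset(c(normal = 122, PD = 83, ET = 30), seed = 2)
  sp3 <- holdout_split(fd3, n_test_per_class = 10, seed = 5)
  frac3 <- nrow(sp3$trainval$meta) / nrow(fd3$meta)
  expect_equal(frac3, 205 / 235)
  expect_equal(round(100 * frac3), 87)

  # determinism and subject hygiene
  sp2b <- holdout_split(fd2, n_test_per_class = 10, seed = 5)
  expect_identical(sp2$test$meta$id, sp2b$test$meta$id)
  expect_length(intersect(sp3$test$meta$subject, sp3$trainval$meta$subject), 0L)

  expect_error(holdout_split(make_toy_dataset(c(PD = 8, ET = 30)), 10),
               "cannot hold out")
})

test_that("stratified folds partition the pool with near-equal class proportions", {
  fd <- make_toy_dataset(c(PD = 83, ET = 30), seed = 3)
  tv <- holdout_split(fd, 10, seed = 1)$trainval  # 73 PD + 20 ET = 93
  plan <- make_folds(tv, k = 5, seed = 2)
  sizes <- lengths(plan$folds)
  expect_true(all(sizes %in% c(18L, 19L)))      # 93 = 3 x 19 + 2 x 18
  expect_setequal(unlist(plan$folds), tv$meta$id)
  expect_equal(sum(sizes), 93L)
  # per-class counts within one of the even share
  for (f in plan$folds) {
    labs <- tv$meta$label[match(f, tv$meta$id)]
    expect_lte(abs(sum(labs == 1) - 73 / 5), 1)
    expect_lte(abs(sum(labs == 2) - 20 / 5), 1)
  }
  expect_error(make_folds(make_toy_dataset(c(PD = 4, ET = 20)), k = 5),
               "at least k")
})

test_that("time slicing preserves shape and varies the start position", {
  fd <- make_toy_dataset(c(PD = 1), frames = 37, feats = 6, seed = 4)
  x <- fd$sequences[[1]]

  # full-length slice is the identity (offset is forced to zero)
  expect_equal(time_slice(x, augmentation_config(c(1, 1)), seed = 3), x)

  cfg <- augmentation_config()
  set.seed(10)
  starts <- integer(200)
  for (i in 1:200) {
    y <- time_slice(x, cfg)
    expect_equal(dim(y), dim(x))
    expect_identical(attr(y, "label"), attr(x, "label"))
    nz <- which(rowSums(abs(y)) > 0)
    # non-slice frames are exactly zero and the slice is contiguous
    expect_true(all(diff(nz) == 1))
    starts[i] <- nz[1]
  }
  expect_gte(length(unique(starts)), 10L)

  expect_error(augmentation_config(c(0.9, 0.2)), "frac_range")
  expect_error(time_slice(x[1, , drop = FALSE], cfg), "at least 2 frames")
})

test_that("oversampling balances training rotations at the study's counts", {
  # the 58 PD / 20 ET rotation balances to 116
  fd <- make_toy_dataset(c(PD = 58, ET = 20), seed = 5, two_frac = 0)
  bal <- oversample_balance(fd, seed = 6)
  expect_equal(nrow(bal$meta), 116L)
  expect_equal(as.vector(table(bal$meta$label)), c(58L, 58L))
  # originals untouched, augmented entries carry provenance
  expect_true(all(fd$meta$id %in% bal$meta$id))
  aug <- bal$meta[bal$meta$augmented, ]
  expect_equal(nrow(aug), 38L)
  expect_true(all(aug$source %in% fd$meta$id[fd$meta$label == 2]))
  expect_identical(bal$sequences[fd$meta$id], fd$sequences)

  # three-class rotations at the study's sizes balance to 267-270
  for (n_norm in c(89, 90)) {
    rot <- make_toy_dataset(c(normal = n_norm, PD = 58, ET = 16), seed = n_norm,
                            two_frac = 0)
    b3 <- oversample_balance(rot, seed = 1)
    expect_true(nrow(b3$meta) >= 267 && nrow(b3$meta) <= 270)
    expect_equal(length(unique(table(b3$meta$label))), 1L)
  }

  # already balanced input is returned unchanged; one class errors
  eq <- make_toy_dataset(c(PD = 10, ET = 10), seed = 8)
  expect_identical(oversample_balance(eq, seed = 1), eq)
  expect_error(oversample_balance(make_toy_dataset(c(PD = 10)), seed = 1),
               "at least two classes")
})

test_that("seeded sampling operations reproduce and vary with the seed", {
  fd <- make_toy_dataset(c(PD = 30, ET = 30), seed = 9)
  expect_identical(make_folds(fd, 5, seed = 4)$folds,
                   make_folds(fd, 5, seed = 4)$folds)
  expect_false(identical(make_folds(fd, 5, seed = 4)$folds,
                         make_folds(fd, 5, seed = 5)$folds))
  x <- fd$sequences[[1]]
  expect_identical(time_slice(x, seed = 7), time_slice(x, seed = 7))
  expect_false(identical(time_slice(x, seed = 7), time_slice(x, seed = 8)))
})

test_that("augmented sequences never reach the held-out side", {
  fd <- make_toy_dataset(c(PD = 20, ET = 12), seed = 10)
  bal <- oversample_balance(fd, seed = 2)
  sp <- holdout_split(bal, n_test_per_class = 5, seed = 3)
  expect_false(any(sp$test$meta$augmented))
  expect_false(any(sp$test$meta$id %in% bal$meta$id[bal$meta$augmented]))
})
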