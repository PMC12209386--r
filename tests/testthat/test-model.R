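test_that("the LSTM cell reproduces hand-evaluated gate equations", {
  # all-zero input, states and weights: sigma(0) = 0.5, tanh(0) = 0
  p0 <- list(U = matrix(0, 2, 12), W = matrix(0, 3, 12), b = rep(0, 12), hidden = 3L)
  s0 <- lstm_step(c(0, 0), rep(0, 3), rep(0, 3), p0)
  expect_equal(unname(s0$i[1, ]), rep(0.5, 3))
  expect_equal(unname(s0$f[1, ]), rep(0.5, 3))
  expect_equal(unname(s0$o[1, ]), rep(0.5, 3))
  expect_true(all(s0$cbar == 0) && all(s0$c == 0) && all(s0$h == 0))

  # scalar cell, unit weights, no bias: oracle evaluated term by term
  p1 <- list(U = matrix(1, 1, 4), W = matrix(1, 1, 4), b = NULL, hidden = 1L)
  s1 <- lstm_step(1, 0, 0, p1)
  sig1 <- 1 / (1 + exp(-1))
  c_exp <- sig1 * tanh(1)
  expect_equal(drop(s1$i), sig1, tolerance = 1e-12)
  expect_equal(drop(s1$cbar), tanh(1), tolerance = 1e-12)
  expect_equal(drop(s1$c), c_exp, tolerance = 1e-12)
  expect_equal(drop(s1$h), sig1 * tanh(c_exp), tolerance = 1e-12)
  expect_equal(drop(s1$h), 0.36961, tolerance = 1e-4)

  # gate ranges hold for arbitrary weights and inputs
  set.seed(12)
  pr <- list(U = matrix(rnorm(5 * 16, sd = 2), 5, 16),
             W = matrix(rnorm(4 * 16, sd = 2), 4, 16),
             b = rnorm(16), hidden = 4L)
  sr <- lstm_step(matrix(rnorm(30 * 5), 30, 5), matrix(rnorm(120), 30, 4),
                  matrix(rnorm(120), 30, 4), pr)
  expect_true(all(sr$i > 0 & sr$i < 1))
  expect_true(all(sr$f > 0 & sr$f < 1))
  expect_true(all(sr$o > 0 & sr$o < 1))
  expect_true(all(sr$cbar > -1 & sr$cbar < 1))

  expect_error(lstm_step(c(1, 2, 3), 0, 0, p1), "input width")
})

test_that("hidden aggregation is the literal sum over time", {
  h <- rbind(c(1, 0.5), c(2, -1), c(3, 0.25))
  expect_equal(aggregate_hidden(h), c(6, -0.25))
  expect_equal(aggregate_hidden(h[1, , drop = FALSE]), h[1, ])
  expect_equal(aggregate_hidden(h[sample(3), ]), aggregate_hidden(h))
  expect_error(aggregate_hidden(h[0, , drop = FALSE]), "empty")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(31)
  D <- 4L; H <- 3L; C <- 2L
  cell <- with_seed(31, lstm_params(D, H))
  params <- list(lstm = list(U = cell$U, W = cell$W, b = cell$b),
                 head = with_seed(32, subtremor:::.init_head(H, 4, C)))
  iface <- subtremor:::.lstm_model_interface(params, list(mu = rep(0, D), sd = rep(1, D)), 0, H)
  x <- list(matrix(rnorm(5 * D), 5, D), matrix(rnorm(5 * D), 5, D))
  y <- c(1L, 2L)
  lossfn <- function(p) {
    probs <- subtremor:::.softmax(iface$forward(p, x)$logits)
    -mean(log(probs[cbind(1:2, y)]))
  }
  fw <- iface$forward(params, x, train = TRUE)
  probs <- subtremor:::.softmax(fw$logits)
  gr <- iface$backward(params, fw$cache, (probs - diag(C)[y, ]) / 2)
  check <- function(analytic, get, set) {
    eps <- 1e-6
    num <- (lossfn(set(params, get(params) + eps)) -
            lossfn(set(params, get(params) - eps))) / (2 * eps)
    expect_equal(analytic, num, tolerance = 1e-5)
  }
  check(gr$lstm$U[2, 5], function(p) p$lstm$U[2, 5],
        function(p, v) { p$lstm$U[2, 5] <- v; p })
  check(gr$lstm$W[1, 10], function(p) p$lstm$W[1, 10],
        function(p, v) { p$lstm$W[1, 10] <- v; p })
  check(gr$lstm$b[7], function(p) p$lstm$b[7],
        function(p, v) { p$lstm$b[7] <- v; p })
  check(gr$head[[1]]$W[2, 3], function(p) p$head[[1]]$W[2, 3],
        function(p, v) { p$head[[1]]$W[2, 3] <- v; p })
  check(gr$head[[2]]$b[1], function(p) p$head[[2]]$b[1],
        function(p, v) { p$head[[2]]$b[1] <- v; p })
})

test_that("forward passes emit valid, deterministic probability simplexes", {
  set.seed(13)
  x <- lapply(1:6, function(i) matrix(rnorm(37 * 10), 37, 10))
  y <- rep(c(1L, 2L, 0L), 2)
  fit <- tremor_lstm(x, y, hidden = 8, fc = 6, max_epochs = 3,
                     validation = NULL, seed = 2)
  p <- predict(fit, x, type = "prob")
  expect_equal(dim(p), c(6L, 3L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_identical(colnames(p), c("normal", "PD", "ET"))
  # duplicate inputs give identical rows in evaluation mode
  p2 <- predict(fit, list(x[[1]], x[[1]]), type = "prob")
  expect_identical(p2[1, ], p2[2, ])
  # class output uses the 0/1/2 coding
  expect_true(all(predict(fit, x) %in% 0:2))
  expect_error(predict(fit, list(matrix(0, 37, 9))), "width")
})

test_that("a wide enough model interpolates a tiny separable set", {
  set.seed(14)
  # two classes separated by the mean level of a noisy sequence
  mk <- function(mu) matrix(rnorm(20 * 5, mean = mu, sd = 0.3), 20, 5)
  x <- c(lapply(1:10, function(i) mk(0)), lapply(1:10, function(i) mk(1)))
  y <- rep(c(0L, 1L), each = 10)
  fit <- tremor_lstm(x, y, hidden = 12, fc = 10, max_epochs = 200,
                     validation = NULL, batch_size = 10, seed = 3)
  expect_equal(mean(predict(fit, x) == y), 1.0)
})

test_that("early stopping fires and restores the best-validation weights", {
  set.seed(15)
  mk <- function(mu) matrix(rnorm(10 * 4, mean = mu, sd = 0.3), 10, 4)
  x <- c(lapply(1:12, function(i) mk(0)), lapply(1:12, function(i) mk(1.5)))
  y <- rep(c(0L, 1L), each = 12)
  # corrupted validation labels force validation accuracy to stay poor
  vx <- c(lapply(1:6, function(i) mk(0)), lapply(1:6, function(i) mk(1.5)))
  vy <- rep(c(1L, 0L), each = 6)
  fit <- tremor_lstm(x, y, hidden = 6, fc = 4, max_epochs = 400, patience = 5,
                     validation = list(x = vx, y = vy), seed = 4)
  expect_lt(nrow(fit$history), 400L)  # stopped well before the budget
  expect_lte(nrow(fit$history), fit$best_epoch + 5L)
})

test_that("training histories are bitwise identical under a fixed seed", {
  set.seed(16)
  x <- lapply(1:12, function(i) matrix(rnorm(8 * 4), 8, 4))
  y <- rep(c(0L, 1L), 6)
  f1 <- tremor_lstm(x, y, hidden = 5, fc = 4, max_epochs = 10, dropout = 0.2,
                    validation = 0.25, seed = 9)
  f2 <- tremor_lstm(x, y, hidden = 5, fc = 4, max_epochs = 10, dropout = 0.2,
                    validation = 0.25, seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  f3 <- tremor_lstm(x, y, hidden = 5, fc = 4, max_epochs = 10, dropout = 0.2,
                    validation = 0.25, seed = 10)
  expect_false(identical(f1$history, f3$history))
})

test_that("hyperparameter search samples inside the tuned ranges", {
  space <- search_space()
  seen <- list()
  res <- hyperparameter_search(space, function(cfg) {
    seen[[length(seen) + 1L]] <<- cfg
    -abs(cfg$hidden - 150)  # prefer mid-range widths
  }, budget = 10, seed = 21)
  expect_equal(nrow(res$trials), 10L)
  expect_true(all(res$trials$hidden %% 10 == 0))
  expect_true(all(res$trials$hidden >= 10 & res$trials$hidden <= 300))
  expect_true(all(res$trials$dropout >= 1e-6 & res$trials$dropout <= 1))
  expect_true(all(res$trials$l2 >= 1e-5 & res$trials$l2 <= 1))
  expect_true(all(res$trials$batch_size %in% seq(16, 128, 4)))
  expect_true(all(res$trials$n_fc %in% 1:3))
  expect_true(all(res$trials$optimizer %in% c("sgd", "adam")))
  expect_equal(res$best_score, max(res$trials$score))
  b1 <- hyperparameter_search(space, function(cfg) cfg$hidden, budget = 1, seed = 3)
  expect_equal(b1$best_score, b1$trials$score[1])
  expect_error(hyperparameter_search(space, identity, budget = 0), "at least 1")
})

test_that("the conv-LSTM baseline has the printed layer arithmetic", {
  m <- build_baseline_convlstm(input_shape = c(1300, 3), n_classes = 2)
  expect_equal(unname(m$layer_shapes["conv1"]), 1281)  # 1300 - 20 + 1
  expect_equal(unname(m$layer_shapes["pool1"]), 640)
  expect_equal(unname(m$layer_shapes["conv2"]), 631)   # 640 - 10 + 1
  expect_equal(unname(m$layer_shapes["pool2"]), 315)
  expect_equal(dim(m$params$conv1$W), c(20L, 3L, 30L))
  expect_equal(dim(m$params$conv2$W), c(10L, 30L, 30L))

  # forward on zeros returns a valid simplex
  fw <- subtremor:::.convlstm_forward(m$params, list(matrix(0, 1300, 3)), FALSE, m)
  probs <- subtremor:::.softmax(fw$logits)
  expect_equal(sum(probs), 1, tolerance = 1e-6)
  expect_true(all(probs >= 0))

  expect_error(build_baseline_convlstm(input_shape = c(15, 3)), "shorter")
})

test_that("the baseline trains with the shared loop and learns a tiny contrast", {
  set.seed(18)
  mk <- function(f) {
    t <- (0:119) / 100
    matrix(sin(2 * pi * f * t + rnorm(1)), 120, 2) + matrix(rnorm(240, sd = 0.1), 120, 2)
  }
  x <- c(lapply(1:8, function(i) mk(5)), lapply(1:8, function(i) mk(12)))
  y <- rep(c(1L, 2L), each = 8)
  m <- build_baseline_convlstm(input_shape = c(120, 2), filters = 4,
                               kernels = c(9, 5), hidden = 6, fc = 8,
                               n_classes = 2, seed = 5)
  fit <- train_convlstm(m, x, y, batch_size = 8, max_epochs = 40, lr = 3e-3,
                        seed = 6)
  expect_gte(mean(predict(fit, x) == y), 0.9)
  p <- predict(fit, x, type = "prob")
  expect_equal(rowSums(p), rep(1, 16), tolerance = 1e-6)
})
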