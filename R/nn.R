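# Shared neural-network internals: parameter initialisation, the dense
# ReLU/softmax head, Adam, and the mini-batch training loop used by both the
# LSTM classifier and the convolutional-LSTM baseline. Everything is plain
# matrix arithmetic so training is exactly reproducible under one seed.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.relu <- function(x) pmax(x, 0)

.glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# ---- dense head: [ReLU ->] (FC -> ReLU)* -> FC -> logits ------------------

.init_head <- function(n_in, fc_widths, n_classes) {
  dims <- c(n_in, fc_widths, n_classes)
  lapply(seq_len(length(dims) - 1L), function(i) {
    list(W = .glorot(dims[i], dims[i + 1L]), b = rep(0, dims[i + 1L]))
  })
}

# a: B x n_in activations entering the head (already ReLU'd aggregate).
# dropout is inverted; masks are drawn here so backward can reuse them.
.head_forward <- function(head, a, dropout = 0, train = FALSE) {
  cache <- list(inputs = list(), masks = list())
  n_layers <- length(head)
  for (i in seq_len(n_layers)) {
    if (train && dropout > 0) {
      mask <- matrix(stats::rbinom(length(a), 1L, 1 - dropout), nrow(a)) / (1 - dropout)
      a <- a * mask
      cache$masks[[i]] <- mask
    }
    cache$inputs[[i]] <- a
    z <- sweep(a %*% head[[i]]$W, 2L, head[[i]]$b, "+")
    a <- if (i < n_layers) .relu(z) else z
    cache$pre <- z
  }
  list(logits = a, cache = cache)
}

.head_backward <- function(head, cache, dlogits) {
  grads <- vector("list", length(head))
  da <- dlogits
  for (i in rev(seq_along(head))) {
    a_in <- cache$inputs[[i]]
    grads[[i]] <- list(W = crossprod(a_in, da), b = colSums(da))
    da <- da %*% t(head[[i]]$W)
    if (length(cache$masks) >= i && !is.null(cache$masks[[i]])) da <- da * cache$masks[[i]]
    if (i > 1L) {
      prev_out <- cache$inputs[[i]]  # post-ReLU (and mask) input to layer i
      da <- da * (prev_out > 0)
    }
  }
  list(grads = grads, dinput = da)
}

# ---- parameter tree utilities ---------------------------------------------

.map_params <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- if (is.null(b)) lapply(seq_along(a), function(i) .map_params(f, a[[i]]))
           else lapply(seq_along(a), function(i) .map_params(f, a[[i]], b[[i]]))
    names(out) <- names(a)
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

.zeros_like <- function(p) .map_params(function(x) x * 0, p)

.adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .map_params(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .map_params(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- .map_params(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                      state$m, state$v)
  list(params = .map_params(`-`, params, step), state = state)
}

.sgd_update <- function(params, grads, lr) {
  .map_params(function(p, g) p - lr * g, params, grads)
}

# L2 (weight decay) on weight matrices only, never biases.
.add_l2 <- function(grads, params, lambda, skip = "b") {
  if (lambda <= 0) return(grads)
  walk <- function(g, p) {
    if (is.list(g)) {
      out <- lapply(seq_along(g), function(i) {
        if (!is.null(names(g)) && names(g)[i] %in% skip) g[[i]]
        else walk(g[[i]], p[[i]])
      })
      names(out) <- names(g)
      out
    } else g + lambda * p
  }
  walk(grads, params)
}

# ---- generic mini-batch trainer -------------------------------------------

# model: list with $params and functions $forward(params, x, train) ->
# list(logits, cache); $backward(params, cache, dlogits) -> grads (tree
# matching params). x is a list of per-sample matrices; y integer class
# index (1-based).
.nn_train_loop <- function(model, x, y, val_x, val_y, config) {
  n <- length(x)
  n_classes <- config$n_classes
  params <- model$params
  adam <- list(t = 0L, m = .zeros_like(params), v = .zeros_like(params))
  best <- list(acc = -Inf, params = params, epoch = 0L)
  wait <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     train_acc = numeric(0), val_acc = numeric(0))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    total_loss <- 0; n_correct <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      fw <- model$forward(params, x[idx], train = TRUE)
      probs <- .softmax(fw$logits)
      onehot <- diag(n_classes)[y[idx], , drop = FALSE]
      loss <- -mean(log(pmax(rowSums(probs * onehot), 1e-12)))
      if (!is.finite(loss)) stop("training diverged: non-finite loss at epoch ", epoch)
      total_loss <- total_loss + loss * length(idx)
      n_correct <- n_correct + sum(max.col(probs, ties.method = "first") == y[idx])
      dlogits <- (probs - onehot) / length(idx)
      grads <- model$backward(params, fw$cache, dlogits)
      grads <- .add_l2(grads, params, config$l2)
      if (config$optimizer == "adam") {
        upd <- .adam_update(params, grads, adam, config$lr)
        params <- upd$params; adam <- upd$state
      } else {
        params <- .sgd_update(params, grads, config$lr)
      }
    }
    val_acc <- if (length(val_x)) {
      probs <- .softmax(model$forward(params, val_x, train = FALSE)$logits)
      mean(max.col(probs, ties.method = "first") == val_y)
    } else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch, loss = total_loss / n,
                                   train_acc = n_correct / n, val_acc = val_acc))
    if (length(val_x)) {
      if (val_acc > best$acc + 1e-12) {
        best <- list(acc = val_acc, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    } else {
      best <- list(acc = hist$train_acc[epoch], params = params, epoch = epoch)
    }
  }
  list(params = best$params, best_epoch = best$epoch, history = hist)
}
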