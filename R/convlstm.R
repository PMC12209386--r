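#' Convolutional-LSTM reference architecture
#'
#' The comparison architecture: a 1-D CNN feature extractor feeding an LSTM.
#' Layer stack: convolution (30 filters, length 20) -> ReLU -> max-pool
#' (width 2) -> convolution (30 filters, length 10) -> ReLU -> max-pool
#' (width 2) -> LSTM -> summed aggregate -> ReLU -> fully connected ->
#' softmax. Its default input is the trio of preprocessed scalar
#' displacement series (1300 samples x 3 channels); it is trained by the
#' same mini-batch loop as the main classifier.
#'
#' @name convlstm
NULL

.conv1d_forward <- function(x, W, b) {
  # x: L x C; W: K x C x F; valid convolution -> (L - K + 1) x F
  K <- dim(W)[1]; L_out <- nrow(x) - K + 1L
  if (L_out < 1L) stop("input shorter than the convolution kernel")
  out <- matrix(rep(b, each = L_out), L_out, dim(W)[3])
  for (k in seq_len(K)) {
    out <- out + x[k:(k + L_out - 1L), , drop = FALSE] %*% W[k, , ]
  }
  out
}

.conv1d_backward <- function(x, W, dout) {
  K <- dim(W)[1]; L_out <- nrow(dout)
  dW <- W * 0
  dx <- x * 0
  for (k in seq_len(K)) {
    sl <- k:(k + L_out - 1L)
    dW[k, , ] <- crossprod(x[sl, , drop = FALSE], dout)
    dx[sl, ] <- dx[sl, ] + dout %*% t(W[k, , ])
  }
  list(dW = dW, db = colSums(dout), dx = dx)
}

.maxpool_forward <- function(x, width = 2L) {
  L_out <- nrow(x) %/% width
  idx <- matrix(0L, L_out, ncol(x))
  out <- matrix(0, L_out, ncol(x))
  for (t in seq_len(L_out)) {
    block <- x[(t - 1L) * width + seq_len(width), , drop = FALSE]
    w <- max.col(t(block), ties.method = "first")
    idx[t, ] <- (t - 1L) * width + w
    out[t, ] <- block[cbind(w, seq_len(ncol(x)))]
  }
  list(out = out, idx = idx)
}

.maxpool_backward <- function(dout, idx, L_in) {
  dx <- matrix(0, L_in, ncol(dout))
  for (j in seq_len(ncol(dout))) dx[idx[, j], j] <- dout[, j]
  dx
}

#' Build the convolutional-LSTM baseline
#'
#' @param input_shape `c(length, channels)` of the input series (default
#'   `c(1300, 3)`: the three sensors' displacement magnitudes).
#' @param filters number of filters in both convolution layers.
#' @param kernels lengths of the first and second convolution kernels.
#' @param pool max-pooling width.
#' @param hidden LSTM hidden units.
#' @param fc widths of the inner fully connected layers.
#' @param n_classes output classes (2 or 3).
#' @param seed seed for weight initialisation.
#' @return An object of class `convlstm_model`; `layer_shapes` records the
#'   output length of every layer for inspection.
#' @export
build_baseline_convlstm <- function(input_shape = c(1300, 3), filters = 30,
                                    kernels = c(20, 10), pool = 2,
                                    hidden = 30, fc = 30, n_classes = 2,
                                    seed = 1) {
  L <- input_shape[1]; C <- input_shape[2]
  if (L < kernels[1]) stop("input shorter than the first convolution kernel")
  l1 <- L - kernels[1] + 1L
  p1 <- l1 %/% pool
  l2 <- p1 - kernels[2] + 1L
  p2 <- l2 %/% pool
  if (p2 < 1L) stop("input too short for the convolution/pooling stack")
  params <- with_seed(seed, {
    cell <- lstm_params(filters, hidden)
    list(conv1 = list(W = array(stats::runif(kernels[1] * C * filters, -1, 1) *
                                  sqrt(6 / (kernels[1] * C + filters)),
                                dim = c(kernels[1], C, filters)),
                      b = rep(0, filters)),
         conv2 = list(W = array(stats::runif(kernels[2] * filters * filters, -1, 1) *
                                  sqrt(6 / (kernels[2] * filters + filters)),
                                dim = c(kernels[2], filters, filters)),
                      b = rep(0, filters)),
         lstm = list(U = cell$U, W = cell$W, b = cell$b),
         head = .init_head(hidden, fc, n_classes))
  })
  structure(list(params = params, input_shape = input_shape, pool = pool,
                 hidden = hidden, n_classes = n_classes,
                 norm = list(mu = rep(0, C), sd = rep(1, C)), dropout = 0,
                 layer_shapes = c(input = L, conv1 = l1, pool1 = p1,
                                  conv2 = l2, pool2 = p2)),
            class = "convlstm_model")
}

#' @export
print.convlstm_model <- function(x, ...) {
  s <- x$layer_shapes
  cat(sprintf("<convlstm_model> %d x %d input -> conv %d -> pool %d -> conv %d -> pool %d -> LSTM(%d) -> head (%d classes)\n",
              x$input_shape[1], x$input_shape[2], s["conv1"], s["pool1"],
              s["conv2"], s["pool2"], x$hidden, x$n_classes))
  invisible(x)
}

.convlstm_forward <- function(params, x, train, model) {
  pool <- model$pool
  cnn <- lapply(x, function(xi) {
    xi <- sweep(sweep(xi, 2L, model$norm$mu), 2L, model$norm$sd, "/")
    c1 <- .conv1d_forward(xi, params$conv1$W, params$conv1$b)
    r1 <- .relu(c1)
    m1 <- .maxpool_forward(r1, pool)
    c2 <- .conv1d_forward(m1$out, params$conv2$W, params$conv2$b)
    r2 <- .relu(c2)
    m2 <- .maxpool_forward(r2, pool)
    list(x = xi, c1 = c1, m1 = m1, c2 = c2, m2 = m2)
  })
  seqs <- lapply(cnn, function(s) s$m2$out)
  lf <- .lstm_forward_batch(list(lstm = params$lstm, head = params$head),
                            seqs,
                            train = train,
                            norm = list(mu = rep(0, ncol(seqs[[1]])),
                                        sd = rep(1, ncol(seqs[[1]]))),
                            dropout = model$dropout, hidden = model$hidden)
  list(logits = lf$logits, cache = list(cnn = cnn, lstm = lf$cache))
}

.convlstm_backward <- function(params, cache, dlogits, model) {
  H <- model$hidden
  lstm_par <- list(lstm = params$lstm, head = params$head)
  gr <- .lstm_backward_batch_dx(lstm_par, cache$lstm, dlogits, H)
  pool <- model$pool
  g_c1W <- params$conv1$W * 0; g_c1b <- params$conv1$b * 0
  g_c2W <- params$conv2$W * 0; g_c2b <- params$conv2$b * 0
  for (b in seq_along(cache$cnn)) {
    s <- cache$cnn[[b]]
    dseq <- gr$dx[[b]]                           # T' x filters
    dr2 <- .maxpool_backward(dseq, s$m2$idx, nrow(s$c2))
    dc2 <- dr2 * (s$c2 > 0)
    bk2 <- .conv1d_backward(s$m1$out, params$conv2$W, dc2)
    g_c2W <- g_c2W + bk2$dW; g_c2b <- g_c2b + bk2$db
    dr1 <- .maxpool_backward(bk2$dx, s$m1$idx, nrow(s$c1))
    dc1 <- dr1 * (s$c1 > 0)
    bk1 <- .conv1d_backward(s$x, params$conv1$W, dc1)
    g_c1W <- g_c1W + bk1$dW; g_c1b <- g_c1b + bk1$db
  }
  list(conv1 = list(W = g_c1W, b = g_c1b),
       conv2 = list(W = g_c2W, b = g_c2b),
       lstm = gr$grads$lstm, head = gr$grads$head)
}

.convlstm_model_interface <- function(model) {
  list(params = model$params,
       forward = function(params, x, train = FALSE)
         .convlstm_forward(params, x, train, model),
       backward = function(params, cache, dlogits)
         .convlstm_backward(params, cache, dlogits, model))
}

#' Train the convolutional-LSTM baseline
#'
#' @param model a [build_baseline_convlstm()] model.
#' @param x list of length x channels input matrices.
#' @param y class labels (codes or names).
#' @param validation optional `list(x =, y =)` for early stopping.
#' @param batch_size,optimizer,lr,l2,max_epochs,patience,seed training
#'   settings as in [tremor_lstm()].
#' @return The model with fitted `params`, `history`, `best_epoch` and
#'   `classes`; predict with [predict.convlstm_model()].
#' @export
train_convlstm <- function(model, x, y, validation = NULL, batch_size = 32,
                           optimizer = "adam", lr = 1e-3, l2 = 0,
                           max_epochs = 60, patience = 10, seed = 1) {
  y <- vapply(y, class_code, integer(1))
  classes <- sort(unique(y))
  if (length(classes) != model$n_classes) stop("label count does not match the model head")
  # normalize channels with training-set statistics
  all_rows <- do.call(rbind, x)
  model$norm <- list(mu = colMeans(all_rows),
                     sd = pmax(apply(all_rows, 2L, stats::sd), 1e-8))
  val_x <- list(); val_y <- integer(0)
  if (!is.null(validation)) {
    val_x <- validation$x
    val_y <- match(vapply(validation$y, class_code, integer(1)), classes)
  }
  fit <- with_seed(seed, {
    iface <- .convlstm_model_interface(model)
    .nn_train_loop(iface, x, match(y, classes), val_x, val_y,
                   list(n_classes = length(classes), batch_size = batch_size,
                        optimizer = optimizer, lr = lr, l2 = l2,
                        max_epochs = max_epochs, patience = patience))
  })
  model$params <- fit$params
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$classes <- classes
  model
}

#' @rdname train_convlstm
#' @param object a trained `convlstm_model`.
#' @param newdata list of input matrices.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @export
predict.convlstm_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  fw <- .convlstm_forward(object$params, newdata, train = FALSE, object)
  probs <- .softmax(fw$logits)
  if (!is.null(object$classes)) colnames(probs) <- class_name(object$classes)
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}
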