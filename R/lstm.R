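#' The LSTM cell and sequence classifier
#'
#' The recurrent cell follows the standard gated form: input, forget and
#' output gates by logistic sigmoid of affine maps of the current input and
#' previous hidden state, a tanh candidate cell state, cell update
#' C_t = f_t * C_{t-1} + I_t * Cbar_t, and hidden output
#' h_t = O_t * tanh(C_t). The per-unit hidden activations are aggregated by
#' summation over all time steps before entering the ReLU / fully-connected
#' / softmax head.
#'
#' @name lstm
NULL

#' Initialise LSTM gate parameters
#'
#' Gate weights are stored column-blocked in order (input, forget, output,
#' candidate): `U` is input-to-gate (input_dim x 4*hidden), `W` is
#' recurrent (hidden x 4*hidden), `b` the per-gate biases (zero at
#' initialisation; set `bias = FALSE` for the bias-free equation form).
#'
#' @param input_dim per-step feature count.
#' @param hidden number of hidden units.
#' @param bias include trainable biases.
#' @return A list of class `lstm_params` with `U`, `W`, `b`, `hidden`.
#' @export
lstm_params <- function(input_dim, hidden, bias = TRUE) {
  structure(list(U = .glorot(input_dim, 4L * hidden),
                 W = .glorot(hidden, 4L * hidden),
                 b = if (bias) rep(0, 4L * hidden) else NULL,
                 hidden = hidden),
            class = "lstm_params")
}

.gate_cols <- function(hidden) {
  list(i = seq_len(hidden), f = hidden + seq_len(hidden),
       o = 2L * hidden + seq_len(hidden), c = 3L * hidden + seq_len(hidden))
}

#' One LSTM cell step
#'
#' Evaluates the gate equations for a single time step. `x_t` may be a
#' vector (one sample) or a B x input_dim matrix (a batch).
#'
#' @param x_t input vector or matrix at time t.
#' @param h_prev,c_prev previous hidden and cell state (vector or B x hidden
#'   matrix; scalars are recycled).
#' @param params an [lstm_params()].
#' @return List with `h`, `c` and the gate values `i`, `f`, `o`, `cbar`
#'   (each a B x hidden matrix).
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params) {
  if (is.null(dim(x_t))) x_t <- matrix(x_t, nrow = 1L)
  H <- params$hidden
  B <- nrow(x_t)
  as_state <- function(s) {
    if (is.null(dim(s))) matrix(s, B, H, byrow = length(s) == H) else s
  }
  h_prev <- as_state(h_prev); c_prev <- as_state(c_prev)
  if (ncol(x_t) != nrow(params$U)) stop("input width does not match U")
  z <- x_t %*% params$U + h_prev %*% params$W
  if (!is.null(params$b)) z <- sweep(z, 2L, params$b, "+")
  if (!all(is.finite(z))) stop("non-finite pre-activation in LSTM step")
  g <- .gate_cols(H)
  i <- .sigmoid(z[, g$i, drop = FALSE])
  f <- .sigmoid(z[, g$f, drop = FALSE])
  o <- .sigmoid(z[, g$o, drop = FALSE])
  cbar <- tanh(z[, g$c, drop = FALSE])
  c_t <- f * c_prev + i * cbar
  list(h = o * tanh(c_t), c = c_t, i = i, f = f, o = o, cbar = cbar)
}

#' Sum-aggregate hidden activations over time
#'
#' Per hidden unit, the activation entering the classification head is the
#' sum of that unit's hidden outputs over all sequence steps.
#'
#' @param h_seq a T x hidden matrix of hidden states (rows are time steps),
#'   or a list of per-step vectors.
#' @return A vector of length `hidden`.
#' @export
aggregate_hidden <- function(h_seq) {
  if (is.list(h_seq)) h_seq <- do.call(rbind, h_seq)
  if (is.null(dim(h_seq))) h_seq <- matrix(h_seq, nrow = 1L)
  if (nrow(h_seq) == 0L) stop("cannot aggregate an empty hidden sequence")
  colSums(h_seq)
}

# ---- batched forward/backward over a stack of equal-length sequences ------

# x: list of T x D matrices (equal T). Returns B x T x D array.
.stack_sequences <- function(x) {
  Tn <- nrow(x[[1]]); D <- ncol(x[[1]])
  ok <- vapply(x, function(s) nrow(s) == Tn && ncol(s) == D, logical(1))
  if (!all(ok)) stop("all sequences in a batch must share one shape")
  array(unlist(lapply(x, t), use.names = FALSE), dim = c(D, Tn, length(x)))
}

.lstm_forward_batch <- function(params, x, train = FALSE, norm, dropout, hidden) {
  arr <- .stack_sequences(x)              # D x T x B
  D <- dim(arr)[1]; Tn <- dim(arr)[2]; B <- dim(arr)[3]
  H <- hidden
  cell <- c(params$lstm, list(hidden = H))
  h <- matrix(0, B, H); c_t <- matrix(0, B, H)
  steps <- vector("list", Tn)
  agg <- matrix(0, B, H)
  for (t in seq_len(Tn)) {
    xt <- if (B == 1L) matrix(arr[, t, 1], 1L, D) else t(arr[, t, , drop = TRUE])
    xt <- sweep(sweep(xt, 2L, norm$mu), 2L, norm$sd, "/")
    st <- lstm_step(xt, h, c_t, cell)
    steps[[t]] <- c(st, list(x = xt, h_prev = h, c_prev = c_t))
    h <- st$h; c_t <- st$c
    agg <- agg + h
  }
  a0 <- .relu(agg)
  hf <- .head_forward(params$head, a0, dropout = if (train) dropout else 0,
                      train = train)
  list(logits = hf$logits,
       cache = list(steps = steps, agg = agg, a0 = a0, head = hf$cache, B = B))
}

.lstm_backward_batch <- function(params, cache, dlogits, hidden) {
  H <- hidden
  hb <- .head_backward(params$head, cache$head, dlogits)
  dA <- hb$dinput * (cache$agg > 0)      # through the ReLU on the aggregate
  steps <- cache$steps
  Tn <- length(steps)
  dU <- params$lstm$U * 0; dW <- params$lstm$W * 0
  db <- if (!is.null(params$lstm$b)) params$lstm$b * 0 else NULL
  dh_next <- matrix(0, nrow(dA), H); dc_next <- dh_next
  g <- .gate_cols(H)
  for (t in rev(seq_len(Tn))) {
    s <- steps[[t]]
    dh <- dA + dh_next                   # sum aggregation feeds every step
    tc <- tanh(s$c)
    do_ <- dh * tc
    dc <- dc_next + dh * s$o * (1 - tc^2)
    di <- dc * s$cbar
    df <- dc * s$c_prev
    dcb <- dc * s$i
    dc_next <- dc * s$f
    dz <- matrix(0, nrow(dh), 4L * H)
    dz[, g$i] <- di * s$i * (1 - s$i)
    dz[, g$f] <- df * s$f * (1 - s$f)
    dz[, g$o] <- do_ * s$o * (1 - s$o)
    dz[, g$c] <- dcb * (1 - s$cbar^2)
    dU <- dU + crossprod(s$x, dz)
    dW <- dW + crossprod(s$h_prev, dz)
    if (!is.null(db)) db <- db + colSums(dz)
    dh_next <- dz %*% t(params$lstm$W)
  }
  lstm_g <- list(U = dU, W = dW)
  if (!is.null(db)) lstm_g$b <- db
  list(lstm = lstm_g, head = hb$grads)
}

# Variant that also propagates gradients to the inputs (needed when the
# LSTM sits on top of a trainable feature extractor, as in the baseline).
.lstm_backward_batch_dx <- function(params, cache, dlogits, hidden) {
  H <- hidden
  hb <- .head_backward(params$head, cache$head, dlogits)
  dA <- hb$dinput * (cache$agg > 0)
  steps <- cache$steps
  Tn <- length(steps)
  B <- nrow(dA)
  D <- ncol(steps[[1]]$x)
  dU <- params$lstm$U * 0; dW <- params$lstm$W * 0
  db <- if (!is.null(params$lstm$b)) params$lstm$b * 0 else NULL
  dh_next <- matrix(0, B, H); dc_next <- dh_next
  dx_arr <- array(0, dim = c(B, Tn, D))
  g <- .gate_cols(H)
  for (t in rev(seq_len(Tn))) {
    s <- steps[[t]]
    dh <- dA + dh_next
    tc <- tanh(s$c)
    do_ <- dh * tc
    dc <- dc_next + dh * s$o * (1 - tc^2)
    di <- dc * s$cbar
    df <- dc * s$c_prev
    dcb <- dc * s$i
    dc_next <- dc * s$f
    dz <- matrix(0, B, 4L * H)
    dz[, g$i] <- di * s$i * (1 - s$i)
    dz[, g$f] <- df * s$f * (1 - s$f)
    dz[, g$o] <- do_ * s$o * (1 - s$o)
    dz[, g$c] <- dcb * (1 - s$cbar^2)
    dU <- dU + crossprod(s$x, dz)
    dW <- dW + crossprod(s$h_prev, dz)
    if (!is.null(db)) db <- db + colSums(dz)
    dx_arr[, t, ] <- dz %*% t(params$lstm$U)
    dh_next <- dz %*% t(params$lstm$W)
  }
  lstm_g <- list(U = dU, W = dW)
  if (!is.null(db)) lstm_g$b <- db
  dx <- lapply(seq_len(B), function(b) matrix(dx_arr[b, , ], Tn, D))
  list(grads = list(lstm = lstm_g, head = hb$grads), dx = dx)
}

# Trainable parameters: params$lstm (U, W, b) and params$head. The input
# normalisation statistics, dropout probability and hidden size are fixed
# model attributes closed over by the interface.
.lstm_model_interface <- function(params, norm, dropout, hidden) {
  list(params = params,
       forward = function(params, x, train = FALSE)
         .lstm_forward_batch(params, x, train, norm, dropout, hidden),
       backward = function(params, cache, dlogits)
         .lstm_backward_batch(params, cache, dlogits, hidden))
}
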