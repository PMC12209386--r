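#' Quaternion algebra for orientation streams
#'
#' Quaternions are stored as length-4 numeric vectors `c(w, x, y, z)` (the
#' scalar component first), or as n x 4 matrices with one quaternion per row.
#' All operations are vectorised over rows so a whole orientation stream can
#' be processed in one call.
#'
#' @name quaternion
NULL

.as_quat_matrix <- function(q) {
  if (is.null(dim(q))) {
    if (length(q) != 4L) stop("a quaternion has exactly 4 components (w, x, y, z)")
    q <- matrix(q, nrow = 1L)
  }
  if (ncol(q) != 4L) stop("quaternion matrix must have 4 columns (w, x, y, z)")
  if (!all(is.finite(q))) stop("quaternion components must be finite")
  q
}

.quat_shape_out <- function(m, q_in) {
  if (is.null(dim(q_in))) drop(m) else m
}

#' Hamilton product of two quaternions
#'
#' Computes `a` \eqn{\otimes} `b`. Either argument may be a single
#' quaternion or an n x 4 matrix; matrices are multiplied row-wise and a
#' single quaternion is recycled against a matrix.
#'
#' @param a,b length-4 numeric vectors `c(w, x, y, z)` or n x 4 matrices.
#' @return A quaternion (or matrix of quaternions) of the broadcast shape.
#' @examples
#' quat_multiply(c(0, 1, 0, 0), c(0, 0, 1, 0))  # i * j = k
#' @export
quat_multiply <- function(a, b) {
  vec_in <- is.null(dim(a)) && is.null(dim(b))
  a <- .as_quat_matrix(a)
  b <- .as_quat_matrix(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("row counts of quaternion operands do not match")
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  out <- cbind(w = w, x = x, y = y, z = z)
  if (vec_in) drop(out) else out
}

#' Quaternion conjugate
#'
#' Negates the vector part and keeps the scalar part: for
#' \eqn{q = q_0 + q_1 i + q_2 j + q_3 k}, returns
#' \eqn{q^* = q_0 - q_1 i - q_2 j - q_3 k}.
#'
#' @param q a quaternion `c(w, x, y, z)` or an n x 4 matrix.
#' @return The conjugate, same shape as the input.
#' @export
quat_conjugate <- function(q) {
  m <- .as_quat_matrix(q)
  out <- cbind(w = m[, 1], x = -m[, 2], y = -m[, 3], z = -m[, 4])
  .quat_shape_out(out, q)
}

#' Quaternion norm
#' @param q a quaternion or n x 4 matrix.
#' @return Euclidean norm per quaternion.
#' @export
quat_norm <- function(q) {
  m <- .as_quat_matrix(q)
  drop(sqrt(rowSums(m^2)))
}

#' Normalize quaternions to unit norm
#'
#' @param q a quaternion or n x 4 matrix.
#' @param warn_tol warn when any raw norm deviates from 1 by more than this.
#' @return Unit quaternion(s), same shape as the input.
#' @export
quat_normalize <- function(q, warn_tol = 1e-3) {
  m <- .as_quat_matrix(q)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("cannot normalize a zero-norm quaternion")
  if (any(abs(nrm - 1) > warn_tol)) {
    warning(sprintf("quaternion norm deviates from 1 by up to %.3g before renormalization",
                    max(abs(nrm - 1))))
  }
  .quat_shape_out(m / nrm, q)
}

#' Rotate the fixed reference point (1, 0, 0)
#'
#' Maps an orientation quaternion to the image of the reference point
#' \eqn{P = (1, 0, 0)} under the conjugation \eqn{X = q^* P q}, with P
#' embedded as a pure quaternion. Note the conjugation order: this is the
#' passive sense, the mirror of the more common active \eqn{q P q^*}; the two
#' differ only by the direction of rotation, which leaves displacement
#' magnitudes (and hence every downstream feature) unchanged.
#'
#' @param q a unit quaternion or n x 4 matrix (renormalized internally; a
#'   warning is issued when the raw norm is off by more than `1e-3`).
#' @return A 3-vector (or n x 3 matrix) of unit norm.
#' @export
rotate_reference <- function(q) {
  m <- quat_normalize(.as_quat_matrix(q))
  m <- .as_quat_matrix(m)
  P <- c(0, 1, 0, 0)
  out <- quat_multiply(quat_multiply(quat_conjugate(m), P), m)
  out <- .as_quat_matrix(out)[, 2:4, drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  if (is.null(dim(q))) drop(out) else out
}

#' Rotation-matrix form of the reference-point map
#'
#' The 3 x 3 matrix R such that `rotate_reference(q)` equals `R %*% c(1,0,0)`
#' for a unit quaternion. Used as an independent cross-check of the
#' quaternion conjugation arithmetic.
#'
#' @param q a single unit quaternion.
#' @return A 3 x 3 rotation matrix (of the passive, `q* P q`, convention).
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  # transpose of the standard active rotation matrix
  t(matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE))
}
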