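#' Joint angles from relative sensor orientations
#'
#' Wrist angles come from the hand orientation relative to the forearm,
#' elbow angles from the forearm relative to the upper arm. Each relative
#' quaternion is decomposed into intrinsic Z-Y-X Euler angles with the
#' anatomical mapping documented in [euler_zyx()]:
#' flexion-extension about Z, abduction-adduction about Y,
#' pronation-supination about X.
#'
#' @name joint-angles
NULL

#' Intrinsic Z-Y-X Euler decomposition of a unit quaternion
#'
#' Returns angles `(z, y, x)` in radians such that
#' `q = qz(z) (x) qy(y) (x) qx(x)` (Hamilton products of the single-axis
#' quaternions, see [euler_to_quat()]). Axis-to-anatomy mapping used
#' throughout the package: Z carries flexion-extension, Y carries wrist
#' abduction-adduction, X carries elbow pronation-supination.
#'
#' @param q unit quaternion `c(w, x, y, z)` or n x 4 matrix.
#' @return A matrix with columns `z`, `y`, `x` (radians).
#' @export
euler_zyx <- function(q) {
  m <- .as_quat_matrix(quat_normalize(q))
  w <- m[, 1]; x <- m[, 2]; y <- m[, 3]; z <- m[, 4]
  s <- pmin(pmax(2 * (w * y - z * x), -1), 1)  # clamp against roundoff at gimbal lock
  cbind(z = atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2)),
        y = asin(s),
        x = atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2)))
}

#' Compose a quaternion from intrinsic Z-Y-X Euler angles
#'
#' Inverse of [euler_zyx()] away from the pitch singularity.
#'
#' @param z,y,x angles in radians (may be vectors of equal length).
#' @return Unit quaternion(s) `(w, x, y, z)`.
#' @export
euler_to_quat <- function(z, y, x) {
  qz <- cbind(cos(z / 2), 0, 0, sin(z / 2))
  qy <- cbind(cos(y / 2), 0, sin(y / 2), 0)
  qx <- cbind(cos(x / 2), sin(x / 2), 0, 0)
  out <- quat_multiply(quat_multiply(qz, qy), qx)
  if (length(z) == 1L && length(y) == 1L && length(x) == 1L) drop(out) else out
}

#' Extract the four joint-angle series from a recording
#'
#' Computes relative quaternions r_wrist = conj(q_forearm) * q_hand and
#' r_elbow = conj(q_upperarm) * q_forearm per sample, then decomposes each
#' into intrinsic Z-Y-X Euler angles. The wrist contributes
#' flexion-extension (WFE, Z) and abduction-adduction (WAA, Y); the elbow
#' contributes flexion-extension (EFE, Z) and pronation-supination (EPS, X).
#'
#' @param recording a [tremor_recording()] whose three streams share one
#'   time base.
#' @return A `joint_angle_set`: list with `time_s` and the four angle series
#'   `WFE`, `WAA`, `EPS`, `EFE` in radians.
#' @export
joint_angles <- function(recording) {
  st <- recording$streams
  t0 <- st$hand$time_s
  if (!isTRUE(all.equal(t0, st$forearm$time_s)) ||
      !isTRUE(all.equal(t0, st$upperarm$time_s)))
    stop("sensor streams are not aligned on one time base")
  r_wrist <- quat_multiply(quat_conjugate(st$forearm$q), st$hand$q)
  r_elbow <- quat_multiply(quat_conjugate(st$upperarm$q), st$forearm$q)
  ew <- euler_zyx(r_wrist)
  ee <- euler_zyx(r_elbow)
  structure(list(time_s = t0,
                 WFE = ew[, "z"], WAA = ew[, "y"],
                 EPS = ee[, "x"], EFE = ee[, "z"]),
            class = "joint_angle_set")
}

#' @export
print.joint_angle_set <- function(x, ...) {
  rms <- vapply(x[c("WFE", "WAA", "EPS", "EFE")],
                function(a) sqrt(mean(a^2)), numeric(1))
  cat(sprintf("<joint_angle_set> %d samples; RMS (mrad): WFE %.2f, WAA %.2f, EPS %.2f, EFE %.2f\n",
              length(x$time_s), 1000 * rms[1], 1000 * rms[2], 1000 * rms[3], 1000 * rms[4]))
  invisible(x)
}

#' Write a joint-angle set to CSV
#' @param angles a `joint_angle_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_joint_angles <- function(angles, path) {
  utils::write.csv(data.frame(time_s = angles$time_s, WFE = angles$WFE,
                              WAA = angles$WAA, EPS = angles$EPS, EFE = angles$EFE),
                   path, row.names = FALSE)
  invisible(path)
}
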