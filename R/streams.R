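#' Orientation streams and recordings
#'
#' A `quat_stream` is one sensor site's timestamped unit-quaternion series; a
#' `tremor_recording` bundles the three sites (hand dorsum, distal forearm,
#' distal upper arm) for one measurement, optionally with ground-truth joint
#' angles (available for simulated data) and a class label.
#'
#' @name streams
NULL

SENSOR_SITES <- c("hand", "forearm", "upperarm")
CLASS_LEVELS <- c(normal = 0L, PD = 1L, ET = 2L)

#' Construct a quaternion stream
#'
#' @param time_s sample times in seconds, strictly increasing.
#' @param q n x 4 matrix of quaternions (w, x, y, z), one row per sample.
#' @param site sensor site, one of `"hand"`, `"forearm"`, `"upperarm"`.
#' @param rate nominal sampling rate in Hz (default 100).
#' @return An object of class `quat_stream`.
#' @export
quat_stream <- function(time_s, q, site = "hand", rate = 100) {
  q <- .as_quat_matrix(q)
  if (length(time_s) != nrow(q)) stop("time and quaternion lengths differ")
  if (length(time_s) == 0L) stop("empty quaternion stream")
  if (any(diff(time_s) <= 0)) stop("stream timestamps must be strictly increasing")
  site <- match.arg(site, SENSOR_SITES)
  structure(list(time_s = as.numeric(time_s), q = unname(q),
                 site = site, rate = rate),
            class = "quat_stream")
}

#' @export
print.quat_stream <- function(x, ...) {
  cat(sprintf("<quat_stream> site=%s, %d samples @ %g Hz, %.2f s\n",
              x$site, length(x$time_s), x$rate,
              x$time_s[length(x$time_s)] - x$time_s[1]))
  invisible(x)
}

#' @export
length.quat_stream <- function(x) length(x$time_s)

#' Construct a tremor recording
#'
#' @param streams named list with elements `hand`, `forearm`, `upperarm`,
#'   each a [quat_stream()].
#' @param label class label: 0 (normal), 1 (PD) or 2 (ET), or the
#'   corresponding name.
#' @param id recording identifier.
#' @param subject subject identifier (up to two recordings may share one).
#' @param angles optional named list of ground-truth joint-angle series
#'   (`WFE`, `WAA`, `EPS`, `EFE`, radians) on the streams' time base.
#' @param rating optional tremor rating stored by the simulator's
#'   subclinical calibration.
#' @return An object of class `tremor_recording`.
#' @export
tremor_recording <- function(streams, label, id = "rec1", subject = id,
                             angles = NULL, rating = NA_real_) {
  if (!all(SENSOR_SITES %in% names(streams)))
    stop("streams must contain hand, forearm and upperarm")
  streams <- streams[SENSOR_SITES]
  label <- class_code(label)
  structure(list(id = id, subject = subject, label = label,
                 streams = streams, angles = angles, rating = rating),
            class = "tremor_recording")
}

#' @export
print.tremor_recording <- function(x, ...) {
  cat(sprintf("<tremor_recording> id=%s subject=%s class=%s (%d samples/site)\n",
              x$id, x$subject, class_name(x$label),
              length(x$streams$hand$time_s)))
  invisible(x)
}

#' Class label coding
#'
#' The classifier output coding is 0 = normal, 1 = PD, 2 = ET.
#' @param label integer code or class name.
#' @return `class_code()` the integer code; `class_name()` the name.
#' @export
class_code <- function(label) {
  if (is.character(label)) {
    if (!label %in% names(CLASS_LEVELS)) stop("unknown class label: ", label)
    return(unname(CLASS_LEVELS[label]))
  }
  label <- as.integer(label)
  if (!label %in% CLASS_LEVELS) stop("class code must be 0, 1 or 2")
  label
}

#' @rdname class_code
#' @export
class_name <- function(label) names(CLASS_LEVELS)[match(as.integer(label), CLASS_LEVELS)]

#' Read quaternion streams from CSV
#'
#' Expects the columnar dialect with header `time_s,q0,q1,q2,q3,site`,
#' `site` in `hand`/`forearm`/`upperarm`.
#'
#' @param path CSV file path.
#' @param rate nominal rate in Hz.
#' @return Named list of [quat_stream()] objects, one per site present.
#' @export
read_quat_streams <- function(path, rate = 100) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "q0", "q1", "q2", "q3", "site")
  if (!all(need %in% names(df))) stop("stream CSV must have columns ", paste(need, collapse = ","))
  out <- lapply(split(df, df$site), function(d) {
    d <- d[order(d$time_s), ]
    quat_stream(d$time_s, as.matrix(d[, c("q0", "q1", "q2", "q3")]),
                site = d$site[1], rate = rate)
  })
  out[intersect(SENSOR_SITES, names(out))]
}

#' Write quaternion streams to CSV
#'
#' @param streams named list of [quat_stream()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_quat_streams <- function(streams, path) {
  rows <- lapply(streams, function(s) {
    data.frame(time_s = s$time_s, q0 = s$q[, 1], q1 = s$q[, 2],
               q2 = s$q[, 3], q3 = s$q[, 4], site = s$site)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Reference-point displacement of an orientation stream
#'
#' Rotates the fixed reference point (1, 0, 0) by every sample's quaternion
#' and subtracts the rotated point at the first sample, giving the
#' dimensionless tremor displacement X(t) - X(t0); the scalar magnitude
#' series is its per-sample Euclidean norm.
#'
#' @param stream a [quat_stream()].
#' @return An object of class `displacement_series`: list with `time_s`,
#'   `xyz` (n x 3) and `magnitude` (length n; first sample exactly 0).
#' @export
displacement_series <- function(stream) {
  if (!inherits(stream, "quat_stream")) stop("stream must be a quat_stream")
  pts <- rotate_reference(stream$q)
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  xyz <- sweep(pts, 2, pts[1, ])
  xyz[1, ] <- 0  # exact zero at t0 by definition
  structure(list(time_s = stream$time_s, xyz = xyz,
                 magnitude = drop(sqrt(rowSums(xyz^2))),
                 site = stream$site),
            class = "displacement_series")
}

#' @export
print.displacement_series <- function(x, ...) {
  cat(sprintf("<displacement_series> site=%s, %d samples, peak |X| = %.4g\n",
              x$site, length(x$magnitude), max(x$magnitude)))
  invisible(x)
}

#' Write a displacement series to CSV
#' @param d a `displacement_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_displacement <- function(d, path) {
  utils::write.csv(data.frame(time_s = d$time_s, x = d$xyz[, 1], y = d$xyz[, 2],
                              z = d$xyz[, 3], magnitude = d$magnitude),
                   path, row.names = FALSE)
  invisible(path)
}
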