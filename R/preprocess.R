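#' Preprocessing: gap repair, tremor-band filtering, duration standardization
#'
#' Raw orientation streams occasionally lose samples in transmission. The
#' pipeline repairs them by shape-preserving piecewise cubic Hermite
#' interpolation (PCHIP) on each quaternion component, converts to
#' reference-point displacement, applies a zero-phase Butterworth band-pass
#' over the 3-30 Hz tremor band, and truncates every recording to the
#' standard 13 s (1300 samples at 100 Hz). The stage order is fixed:
#' gap repair -> displacement -> band-pass -> truncation.
#'
#' @name preprocess
NULL

#' Preprocessing configuration
#'
#' @param rate sampling rate in Hz.
#' @param band band-pass edges in Hz, `c(low, high)`, `low < high < rate/2`.
#' @param duration_s standard duration in seconds; `duration_s * rate` must
#'   be a whole sample count (1300 under the defaults).
#' @param filter_order Butterworth prototype order (the band-pass has twice
#'   this many poles; applied forward and backward for zero phase).
#' @param truncate_offset sample offset at which truncation starts (0 keeps
#'   the first `duration_s` seconds).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(rate = 100, band = c(3, 30), duration_s = 13,
                              filter_order = 4, truncate_offset = 0) {
  if (!(band[1] < band[2] && band[2] < rate / 2))
    stop("band must satisfy low < high < rate/2")
  n <- duration_s * rate
  if (abs(n - round(n)) > 1e-9) stop("duration_s * rate must be an integer sample count")
  structure(list(rate = rate, band = band, duration_s = duration_s,
                 n_samples = as.integer(round(n)), filter_order = filter_order,
                 truncate_offset = as.integer(truncate_offset)),
            class = "preprocess_config")
}

#' Detect dropped samples in a quaternion stream
#'
#' A gap is flagged wherever consecutive timestamps differ by more than
#' 1.5x the nominal sampling period. Grid indices are counted in sampling
#' periods from the first sample (the first sample has index 0), so a sample
#' missing at t = 1.00 s on a 100 Hz stream starting at t = 0 is grid
#' index 100.
#'
#' @param stream a [quat_stream()].
#' @param tol_factor gap threshold as a multiple of the nominal period.
#' @return Integer vector of missing uniform-grid indices (empty when the
#'   stream is complete).
#' @export
detect_gaps <- function(stream, tol_factor = 1.5) {
  t <- stream$time_s
  if (any(diff(t) <= 0)) stop("stream timestamps must be strictly increasing")
  period <- 1 / stream$rate
  if (!any(diff(t) > tol_factor * period)) return(integer(0))
  grid <- seq(0L, as.integer(round((t[length(t)] - t[1]) / period)))
  present <- as.integer(round((t - t[1]) / period))
  setdiff(grid, present)
}

#' Repair stream gaps by piecewise cubic Hermite interpolation
#'
#' Each quaternion component is interpolated independently onto the uniform
#' grid with shape-preserving PCHIP (no overshoot between retained samples),
#' then every interpolated quaternion is renormalized to unit length.
#' Retained samples are reproduced exactly; a gap-free stream is returned
#' unchanged.
#'
#' @param stream a [quat_stream()] with at least 4 samples.
#' @return A [quat_stream()] on the exact uniform grid.
#' @export
fill_gaps_pchip <- function(stream) {
  if (length(stream$time_s) < 4L)
    stop("need at least 4 samples to interpolate a stream")
  missing <- detect_gaps(stream)
  if (length(missing) == 0L) return(stream)
  period <- 1 / stream$rate
  t0 <- stream$time_s[1]
  n_grid <- as.integer(round((stream$time_s[length(stream$time_s)] - t0) / period)) + 1L
  tg <- t0 + (seq_len(n_grid) - 1L) * period
  qg <- vapply(1:4, function(j) signal::pchip(stream$time_s, stream$q[, j], tg),
               numeric(n_grid))
  # keep retained samples bit-exact, renormalize only what was interpolated
  present <- as.integer(round((stream$time_s - t0) / period)) + 1L
  qg[present, ] <- stream$q
  interp <- setdiff(seq_len(n_grid), present)
  qg[interp, ] <- qg[interp, , drop = FALSE] /
    sqrt(rowSums(qg[interp, , drop = FALSE]^2))
  quat_stream(tg, qg, site = stream$site, rate = stream$rate)
}

#' Zero-phase Butterworth band-pass
#'
#' Designs a Butterworth band-pass at the configured edges and applies it
#' forward and backward, giving zero phase distortion so STFT frame timing
#' is preserved. The series is extended by odd reflection at both ends
#' before filtering (and the extension discarded afterwards) to suppress
#' the start-up transients of the recursive filter.
#'
#' @param series uniform scalar series at `config$rate`.
#' @param config a [preprocess_config()].
#' @return Filtered series, same length.
#' @export
bandpass <- function(series, config = preprocess_config()) {
  bf <- signal::butter(config$filter_order, config$band / (config$rate / 2),
                       type = "pass")
  n <- length(series)
  pad <- 3L * (length(bf$a) - 1L)
  if (n <= pad + 1L)
    stop("series too short for stable zero-phase filtering")
  # DC is out of band; removing it first keeps the reflection transient small
  series <- series - mean(series)
  xp <- c(2 * series[1] - rev(series[2:(pad + 1L)]),
          series,
          2 * series[n] - rev(series[(n - pad):(n - 1L)]))
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  as.numeric(y[pad + seq_len(n)])
}

#' Truncate a series to the standard duration
#'
#' @param series uniform scalar series.
#' @param config a [preprocess_config()]; the result keeps
#'   `config$n_samples` samples starting at `truncate_offset`.
#' @return Series of exactly `config$n_samples` samples.
#' @export
standardize_duration <- function(series, config = preprocess_config()) {
  need <- config$n_samples + config$truncate_offset
  if (length(series) < need) {
    stop(sprintf("recording too short: %.2f s available, %.2f s required",
                 length(series) / config$rate, need / config$rate))
  }
  series[config$truncate_offset + seq_len(config$n_samples)]
}

#' Preprocess one recording into three displacement-magnitude signals
#'
#' Runs the fixed stage order (gap repair, displacement conversion,
#' band-pass, truncation) on each of the three sensor streams.
#'
#' @param recording a [tremor_recording()].
#' @param config a [preprocess_config()].
#' @return Named list (`hand`, `forearm`, `upperarm`) of band-limited
#'   displacement-magnitude series, each `config$n_samples` long.
#' @export
preprocess_recording <- function(recording, config = preprocess_config()) {
  lapply(recording$streams, function(s) {
    s <- fill_gaps_pchip(s)
    mag <- displacement_series(s)$magnitude
    standardize_duration(bandpass(mag, config), config)
  })
}
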