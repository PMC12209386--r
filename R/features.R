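#' STFT magnitude features
#'
#' Each sensor's band-limited displacement-magnitude signal is transformed
#' with a short-time Fourier transform at a fixed resolution of
#' 100/128 = 0.78125 Hz (printing as 0.78 Hz) on the frequency axis and
#' 32/100 = 320 ms on the time axis. Only the magnitude is kept. Bins with
#' centers inside the 3-30 Hz tremor band are retained (35 bins under the
#' defaults) and the three sensors' spectrograms are concatenated per frame,
#' so each 13 s recording becomes a 37-frame sequence of 105 features.
#'
#' @name features
NULL

#' Spectrogram configuration
#'
#' @param rate sampling rate, Hz.
#' @param n_fft transform length in samples (bin spacing = `rate / n_fft`).
#' @param hop frame hop in samples (`hop / rate` seconds between frames).
#' @param window window shape: `"hann"` (periodic) or `"rect"`.
#' @param band analysis band in Hz for [band_select()].
#' @return An object of class `spectrogram_config`.
#' @export
spectrogram_config <- function(rate = 100, n_fft = 128, hop = 32,
                               window = c("hann", "rect"), band = c(3, 30)) {
  window <- match.arg(window)
  structure(list(rate = rate, n_fft = as.integer(n_fft), hop = as.integer(hop),
                 window = window, band = band,
                 bin_hz = rate / n_fft, hop_s = hop / rate),
            class = "spectrogram_config")
}

.stft_window <- function(config) {
  n <- config$n_fft
  switch(config$window,
         hann = 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n)),  # periodic Hann
         rect = rep(1, n))
}

#' One-sided STFT magnitude of a scalar series
#'
#' Frames the series without padding (frame count
#' `floor((N - n_fft) / hop) + 1`), windows each frame, and takes the
#' magnitude of the one-sided discrete Fourier transform
#' (`n_fft / 2 + 1` bins including DC and Nyquist).
#'
#' @param series scalar series, at least `n_fft` samples.
#' @param config a [spectrogram_config()].
#' @return An object of class `spectrogram`: list with `mag`
#'   (frames x bins), `freq` (bin centers, Hz) and `time` (frame start
#'   times, s).
#' @export
stft_magnitude <- function(series, config = spectrogram_config()) {
  n <- length(series)
  if (n < config$n_fft)
    stop("series shorter than one analysis window")
  hop <- config$hop; nf <- config$n_fft
  n_frames <- (n - nf) %/% hop + 1L
  win <- .stft_window(config)
  frames <- vapply(seq_len(n_frames), function(i) {
    series[(i - 1L) * hop + seq_len(nf)] * win
  }, numeric(nf))
  spec <- stats::mvfft(frames)  # columns are frames
  n_bins <- nf %/% 2L + 1L
  mag <- t(Mod(spec[seq_len(n_bins), , drop = FALSE]))
  structure(list(mag = mag,
                 freq = (seq_len(n_bins) - 1L) * config$bin_hz,
                 time = (seq_len(n_frames) - 1L) * config$hop / config$rate,
                 config = config),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d frames x %d bins, %.5g Hz x %g ms resolution\n",
              nrow(x$mag), ncol(x$mag), x$config$bin_hz, 1000 * x$config$hop_s))
  invisible(x)
}

#' Restrict a spectrogram to an analysis band
#'
#' Keeps bins whose center frequency f satisfies `low <= f <= high`. With
#' 0.78125 Hz spacing and the 3-30 Hz band this keeps bin indices 4-38
#' (0-based), i.e. 35 bins.
#'
#' @param spec a [stft_magnitude()] spectrogram.
#' @param band `c(low, high)` in Hz.
#' @return A `spectrogram` restricted to the in-band bins.
#' @export
band_select <- function(spec, band = spec$config$band) {
  keep <- which(spec$freq >= band[1] & spec$freq <= band[2])
  if (length(keep) == 0L) stop("no spectrogram bins fall inside the requested band")
  spec$mag <- spec$mag[, keep, drop = FALSE]
  spec$freq <- spec$freq[keep]
  spec
}

#' Assemble the three-sensor feature sequence
#'
#' Concatenates the in-band bins of the hand, forearm and upper-arm
#' spectrograms per frame, so the per-step feature vector is threefold the
#' per-sensor bin count (105 features under the defaults, over 37 frames).
#'
#' @param hand,forearm,upperarm band-selected [stft_magnitude()]
#'   spectrograms on identical frame and bin grids.
#' @param label class label (0 normal, 1 PD, 2 ET) or name.
#' @return An object of class `feature_seq`: the frames x features matrix
#'   with attributes `label`, `freq` and `site` (per-column provenance).
#' @export
assemble_features <- function(hand, forearm, upperarm, label) {
  specs <- list(hand = hand, forearm = forearm, upperarm = upperarm)
  nfr <- vapply(specs, function(s) nrow(s$mag), integer(1))
  if (length(unique(nfr)) != 1L)
    stop("sensor spectrograms disagree on frame count: ",
         paste(nfr, collapse = "/"))
  grids <- vapply(specs, function(s) isTRUE(all.equal(s$freq, hand$freq)), logical(1))
  if (!all(grids)) stop("sensor spectrograms disagree on the frequency grid")
  mat <- do.call(cbind, lapply(specs, `[[`, "mag"))
  structure(mat,
            label = class_code(label),
            freq = rep(hand$freq, 3L),
            site = rep(names(specs), each = length(hand$freq)),
            class = c("feature_seq", "matrix", "array"))
}

#' @export
print.feature_seq <- function(x, ...) {
  cat(sprintf("<feature_seq> %d frames x %d features, class %s\n",
              nrow(x), ncol(x), class_name(attr(x, "label"))))
  invisible(x)
}

#' Featurize one recording
#'
#' Full per-recording feature path: preprocess the three streams, STFT each
#' displacement-magnitude signal, band-select, and assemble the sequence.
#'
#' @param recording a [tremor_recording()].
#' @param pconfig a [preprocess_config()].
#' @param fconfig a [spectrogram_config()].
#' @return A [assemble_features()] `feature_seq`.
#' @export
featurize_recording <- function(recording, pconfig = preprocess_config(),
                                fconfig = spectrogram_config()) {
  sig <- preprocess_recording(recording, pconfig)
  specs <- lapply(sig, function(s) band_select(stft_magnitude(s, fconfig)))
  assemble_features(specs$hand, specs$forearm, specs$upperarm, recording$label)
}
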