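#' Tremor-rating regression and the subclinical gate
#'
#' A linear regression, fitted in earlier clinical work against the average
#' observational rating of six doctors, maps the log mean-square power of the
#' four hand-arm joint angles to a tremor severity rating:
#'
#' rating = 2.6496 + 0.3071 log(theta_WFE,MS) + 0.0731 log(theta_WAA,MS)
#'                 + 0.1843 log(theta_EPS,MS) + 0.0988 log(theta_EFE,MS)
#'
#' A rating strictly below 0.5 defines subclinical tremor. The log base is
#' configurable (default 10) and angle units default to radians; both only
#' shift the rating by a constant, and the simulator's amplitude calibration
#' is performed under the same defaults so the pipeline is self-consistent.
#'
#' @name tremor-rating
NULL

#' Tremor-rating model coefficients
#'
#' @param intercept regression intercept.
#' @param coefficients named coefficients for `WFE`, `WAA`, `EPS`, `EFE`
#'   (all strictly positive).
#' @param threshold subclinical threshold on the rating (strict `<`).
#' @param log_base base of the logarithm applied to the mean-square powers.
#' @return An object of class `tremor_rating_model`.
#' @export
tremor_rating_model <- function(intercept = 2.6496,
                                coefficients = c(WFE = 0.3071, WAA = 0.0731,
                                                 EPS = 0.1843, EFE = 0.0988),
                                threshold = 0.5, log_base = 10) {
  need <- c("WFE", "WAA", "EPS", "EFE")
  if (!all(need %in% names(coefficients))) stop("coefficients must name WFE, WAA, EPS, EFE")
  if (any(coefficients <= 0)) stop("all rating coefficients must be strictly positive")
  structure(list(intercept = intercept, coefficients = coefficients[need],
                 threshold = threshold, log_base = log_base),
            class = "tremor_rating_model")
}

#' @export
print.tremor_rating_model <- function(x, ...) {
  cat(sprintf("<tremor_rating_model> intercept %.4f; log base %g; subclinical < %.2f\n",
              x$intercept, x$log_base, x$threshold))
  print(x$coefficients)
  invisible(x)
}

#' Mean-square power of a signal
#'
#' The regressor of the tremor-rating model: mean of the squared samples.
#'
#' @param series numeric vector.
#' @return A non-negative scalar.
#' @export
mean_square_power <- function(series) {
  if (length(series) == 0L) stop("empty series")
  mean(series^2)
}

#' Evaluate the tremor-rating regression
#'
#' @param powers named numeric vector of mean-square joint-angle powers
#'   (`WFE`, `WAA`, `EPS`, `EFE`), all strictly positive.
#' @param model a [tremor_rating_model()].
#' @return The scalar rating.
#' @export
tremor_rating <- function(powers, model = tremor_rating_model()) {
  need <- names(model$coefficients)
  if (!all(need %in% names(powers))) stop("powers must name WFE, WAA, EPS, EFE")
  powers <- powers[need]
  bad <- names(powers)[!is.finite(powers) | powers <= 0]
  if (length(bad))
    stop("mean-square power must be strictly positive for: ", paste(bad, collapse = ", "))
  model$intercept + sum(model$coefficients * log(powers, base = model$log_base))
}

#' Rate a recording from its joint angles
#'
#' Band-passes each joint-angle series to the tremor band before taking the
#' mean-square power, so the rating and the spectral features see the same
#' 3-30 Hz content.
#'
#' @param recording a [tremor_recording()]; ground-truth angles are used when
#'   present, otherwise angles are extracted with [joint_angles()].
#' @param model a [tremor_rating_model()].
#' @param config a [preprocess_config()] supplying the band; `NULL` rates the
#'   raw angle series.
#' @return List with `rating`, `subclinical` and the four `powers`.
#' @export
rate_recording <- function(recording, model = tremor_rating_model(),
                           config = preprocess_config()) {
  ang <- recording$angles
  if (is.null(ang)) ang <- joint_angles(recording)
  series <- ang[c("WFE", "WAA", "EPS", "EFE")]
  if (!is.null(config)) series <- lapply(series, bandpass, config = config)
  powers <- vapply(series, mean_square_power, numeric(1))
  r <- tremor_rating(powers, model)
  list(rating = r, subclinical = is_subclinical(r, model), powers = powers)
}

#' Subclinical gate
#'
#' @param rating scalar tremor rating.
#' @param model a [tremor_rating_model()] (supplies the threshold).
#' @return `TRUE` iff `rating < threshold` (strict).
#' @export
is_subclinical <- function(rating, model = tremor_rating_model()) {
  if (!is.finite(rating)) stop("rating must be finite")
  rating < model$threshold
}
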