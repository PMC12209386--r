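#' Synthetic subclinical tremor simulator
#'
#' Generates seeded three-sensor quaternion recordings for the three
#' classes, standing in for the (non-deposited) clinical dataset. Each
#' recording is built from four joint-angle oscillators (WFE, WAA, EPS,
#' EFE) with class-specific spectral character, composed into hand, forearm
#' and upper-arm orientations, amplitude-calibrated until the tremor rating
#' is subclinical (< 0.5), and degraded by seeded transmission-loss sample
#' dropout.
#'
#' Spectral defaults follow the clinical bands (PD rest tremor about
#' 3-9 Hz, ET about 4-14 Hz) but are narrowed to 4-6 Hz (PD) versus
#' 8-11 Hz (ET) so the default preset is reliably separable; the
#' `overlapping` preset uses the full clinical bands. PD signals are less
#' regular (larger cycle-to-cycle frequency jitter) and carry one harmonic;
#' physiological tremor is broadband 8-12 Hz at reduced power.
#'
#' @name simdata
NULL

#' Class-conditional tremor signal model
#'
#' @param class `"PD"`, `"ET"` or `"normal"`.
#' @param preset `"separable"` (default narrowed bands), `"overlapping"`
#'   (full clinical bands) or `"null"` (one shared model for every class, a
#'   leakage control).
#' @param band dominant-frequency band in Hz (overrides the preset).
#' @param amplitude base oscillation amplitude in radians (rescaled later
#'   by the subclinical calibration).
#' @param harmonic relative amplitude of the second harmonic.
#' @param jitter cycle-to-cycle frequency jitter (Hz, random-walk scale);
#'   larger values give the less regular signal typical of low-amplitude PD
#'   tremor.
#' @param am_depth depth of the slow random-walk amplitude modulation.
#' @param noise white-noise floor relative to the oscillation amplitude.
#' @param pink 1/f drift floor relative to the oscillation amplitude.
#' @return An object of class `class_signal_model`.
#' @export
class_signal_model <- function(class = c("PD", "ET", "normal"),
                               preset = c("separable", "overlapping", "null"),
                               band = NULL, amplitude = NULL, harmonic = NULL,
                               jitter = NULL, am_depth = 0.3, noise = 0.15,
                               pink = 0.1) {
  class <- match.arg(class)
  preset <- match.arg(preset)
  defaults <- switch(preset,
    separable = list(PD = list(band = c(4, 6), amplitude = 0.02, harmonic = 0.3, jitter = 0.5),
                     ET = list(band = c(8, 11), amplitude = 0.02, harmonic = 0, jitter = 0.2),
                     normal = list(band = c(8, 12), amplitude = 0.01, harmonic = 0, jitter = 1.0)),
    overlapping = list(PD = list(band = c(3, 9), amplitude = 0.02, harmonic = 0.3, jitter = 0.5),
                       ET = list(band = c(4, 14), amplitude = 0.02, harmonic = 0, jitter = 0.2),
                       normal = list(band = c(8, 12), amplitude = 0.01, harmonic = 0, jitter = 1.0)),
    null = list(PD = list(band = c(5, 9), amplitude = 0.015, harmonic = 0, jitter = 0.5),
                ET = list(band = c(5, 9), amplitude = 0.015, harmonic = 0, jitter = 0.5),
                normal = list(band = c(5, 9), amplitude = 0.015, harmonic = 0, jitter = 0.5)))
  d <- defaults[[class]]
  band <- if (is.null(band)) d$band else band
  if (!(band[1] > 0 && band[2] < 50 && band[1] <= band[2]))
    stop("band edges must lie in (0, 50) Hz")
  amplitude <- if (is.null(amplitude)) d$amplitude else amplitude
  if (amplitude <= 0) stop("amplitude must be positive")
  structure(list(class = class, band = band, amplitude = amplitude,
                 harmonic = if (is.null(harmonic)) d$harmonic else harmonic,
                 jitter = if (is.null(jitter)) d$jitter else jitter,
                 am_depth = am_depth, noise = noise, pink = pink),
            class = "class_signal_model")
}

#' Generate one joint-angle tremor signal
#'
#' A phase-continuous oscillator: the instantaneous frequency performs a
#' mean-reverting random walk inside the model band, the amplitude follows
#' a slow log random walk, and a second harmonic (PD), white noise and a
#' 1/f drift are superimposed.
#'
#' @param model a [class_signal_model()].
#' @param duration seconds.
#' @param rate Hz.
#' @param seed integer seed, or `NULL` for the current stream.
#' @return Numeric angle series in radians, `duration * rate` samples.
#' @export
generate_angle_signal <- function(model, duration = 14, rate = 100, seed = NULL) {
  n <- as.integer(round(duration * rate))
  with_seed(seed, {
    f0 <- stats::runif(1, model$band[1], model$band[2])
    f <- rep(f0, n)
    if (model$jitter > 0) {
      # Ornstein-Uhlenbeck walk pulled back to f0, clipped to the band
      e <- stats::rnorm(n, 0, model$jitter / sqrt(rate))
      dev <- as.numeric(stats::filter(e, 0.995, method = "recursive"))
      f <- pmin(pmax(f0 + dev, model$band[1]), model$band[2])
    }
    phase <- 2 * pi * cumsum(f) / rate
    amp <- model$amplitude
    a <- rep(amp, n)
    if (model$am_depth > 0) {
      walk <- cumsum(stats::rnorm(n, 0, model$am_depth / sqrt(rate)))
      a <- amp * exp(walk - mean(walk))
    }
    sig <- a * sin(phase)
    if (model$harmonic > 0) sig <- sig + model$harmonic * a * sin(2 * phase)
    if (model$noise > 0) sig <- sig + stats::rnorm(n, 0, model$noise * amp)
    if (model$pink > 0) {
      drift <- cumsum(stats::rnorm(n, 0, 1))
      drift <- drift - stats::fitted(stats::lm(drift ~ seq_len(n)))
      sig <- sig + model$pink * amp * drift / max(stats::sd(drift), 1e-12)
    }
    sig
  })
}

#' Encode an angle series as a quaternion stream
#'
#' Single-axis rotation: q(t) = (cos(theta/2), axis * sin(theta/2)).
#'
#' @param theta angle series in radians, |theta| < pi.
#' @param axis unit 3-vector rotation axis.
#' @param rate Hz.
#' @param site sensor site tag.
#' @return A [quat_stream()] of unit quaternions.
#' @export
encode_quaternion_stream <- function(theta, axis = c(0, 0, 1), rate = 100,
                                     site = "hand") {
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-8) stop("rotation axis must have unit length")
  if (any(abs(theta) >= pi)) stop("angles must satisfy |theta| < pi")
  q <- cbind(cos(theta / 2), outer(sin(theta / 2), axis))
  quat_stream((seq_along(theta) - 1L) / rate, q, site = site, rate = rate)
}

#' Simulation configuration
#'
#' @param duration recording length in seconds (>= 13).
#' @param rate sampling rate, Hz.
#' @param dropout_fraction fraction of samples lost in transmission
#'   (seeded, interior samples only; must be < 0.5).
#' @param two_reading_frac fraction of subjects contributing two
#'   recordings.
#' @param rating_target interval inside (0, 0.5) into which the calibrated
#'   tremor rating must fall.
#' @param elbow_scale,upperarm_scale relative amplitude of the elbow
#'   oscillators and of the upper-arm baseline wobble (tremor is
#'   distal-dominant).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 14, rate = 100, dropout_fraction = 0.02,
                       two_reading_frac = 0.4, rating_target = c(0.2, 0.4),
                       elbow_scale = 0.5, upperarm_scale = 0.25) {
  if (duration * rate < 1300) stop("duration must cover at least 13 s at 100 Hz")
  if (dropout_fraction < 0 || dropout_fraction >= 0.5)
    stop("dropout fraction must lie in [0, 0.5)")
  if (!(rating_target[1] > 0 && rating_target[2] < 0.5 &&
        rating_target[1] < rating_target[2]))
    stop("rating target must be an interval inside (0, 0.5)")
  structure(list(duration = duration, rate = rate,
                 dropout_fraction = dropout_fraction,
                 two_reading_frac = two_reading_frac,
                 rating_target = rating_target,
                 elbow_scale = elbow_scale, upperarm_scale = upperarm_scale),
            class = "sim_config")
}

#' Remove samples to emulate transmission loss
#'
#' Seeded random removal of `round(fraction * n)` interior samples; the
#' first and last samples are never removed, so gap repair always
#' interpolates.
#'
#' @param stream a [quat_stream()].
#' @param fraction fraction in `[0, 0.5)`.
#' @param seed integer seed or `NULL`.
#' @return The thinned [quat_stream()].
#' @export
apply_dropout <- function(stream, fraction, seed = NULL) {
  if (fraction < 0 || fraction >= 0.5) stop("dropout fraction must lie in [0, 0.5)")
  n <- length(stream$time_s)
  k <- round(fraction * n)
  if (k == 0) return(stream)
  with_seed(seed, {
    drop_idx <- sample(2:(n - 1L), k)
    quat_stream(stream$time_s[-drop_idx], stream$q[-drop_idx, , drop = FALSE],
                site = stream$site, rate = stream$rate)
  })
}

# Compose the three sensor streams from joint-angle series. The wrist
# rotation carries WFE about Z and WAA about Y; the elbow carries EFE about
# Z and EPS about X; the upper arm wobbles about Y. Streams are exact
# quaternion compositions, so joint_angles() recovers the inputs.
.compose_recording_streams <- function(ang, upper_theta, rate) {
  q_upper <- cbind(cos(upper_theta / 2), 0, sin(upper_theta / 2), 0)
  r_elbow <- euler_to_quat(ang$EFE, rep(0, length(ang$EFE)), ang$EPS)
  r_wrist <- euler_to_quat(ang$WFE, ang$WAA, rep(0, length(ang$WFE)))
  q_forearm <- quat_multiply(q_upper, r_elbow)
  q_hand <- quat_multiply(q_forearm, r_wrist)
  list(hand = quat_stream((seq_len(nrow(q_hand)) - 1L) / rate, q_hand, "hand", rate),
       forearm = quat_stream((seq_len(nrow(q_hand)) - 1L) / rate, q_forearm, "forearm", rate),
       upperarm = quat_stream((seq_len(nrow(q_hand)) - 1L) / rate, q_upper, "upperarm", rate))
}

#' Calibrate a draft recording to subclinical amplitude
#'
#' Rescales all joint-angle series by bisection on a common gain until the
#' tremor rating of the recomposed recording falls inside the configured
#' sub-0.5 target interval, then stores the final rating in the recording.
#'
#' @param draft a [tremor_recording()] carrying ground-truth angles.
#' @param rating_model a [tremor_rating_model()].
#' @param target target rating interval inside (0, 0.5).
#' @param pconfig a [preprocess_config()] for the rating band-pass.
#' @return The calibrated [tremor_recording()] (with `rating` set).
#' @export
calibrate_subclinical <- function(draft, rating_model = tremor_rating_model(),
                                  target = c(0.2, 0.4),
                                  pconfig = preprocess_config()) {
  if (is.null(draft$angles)) stop("calibration needs ground-truth joint angles")
  rate <- draft$streams$hand$rate
  upper_theta <- attr(draft, "upper_theta")
  # the band-pass is linear and the mean square quadratic, so a common gain
  # g scales every power by g^2 exactly; filter once, then bisect on the gain
  base_powers <- vapply(draft$angles[c("WFE", "WAA", "EPS", "EFE")],
                        function(a) mean_square_power(bandpass(a, pconfig)),
                        numeric(1))
  rating_of <- function(log_gain) {
    tremor_rating(base_powers * (10^log_gain)^2, rating_model)
  }
  mid <- mean(target)
  lo <- -4; hi <- 2
  if (rating_of(lo) > mid || rating_of(hi) < mid)
    stop("calibration target unreachable: rating insensitive to amplitude")
  for (i in 1:60) {
    m <- (lo + hi) / 2
    r <- rating_of(m)
    if (r < mid) lo <- m else hi <- m
    if (hi - lo < 1e-10) break
  }
  g <- 10^((lo + hi) / 2)
  final <- rating_of(log10(g))
  if (final < target[1] - 1e-6 || final > target[2] + 1e-6)
    stop("calibration failed to land in the target interval")
  ang <- lapply(draft$angles[c("WFE", "WAA", "EPS", "EFE")], `*`, g)
  streams <- .compose_recording_streams(ang, upper_theta * g, rate)
  rec <- tremor_recording(streams, draft$label, id = draft$id,
                          subject = draft$subject,
                          angles = c(list(time_s = streams$hand$time_s), ang),
                          rating = final)
  attr(rec, "upper_theta") <- upper_theta * g
  rec
}

#' Simulate one labelled recording
#'
#' @param label class (code or name).
#' @param model a [class_signal_model()] for the class.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param id,subject identifiers.
#' @param rating_model a [tremor_rating_model()].
#' @return A calibrated, dropout-degraded [tremor_recording()].
#' @export
simulate_recording <- function(label, model, config = sim_config(), seed = 1,
                               id = "rec1", subject = id,
                               rating_model = tremor_rating_model()) {
  with_seed(seed, {
    gen <- function(scale) scale * generate_angle_signal(model, config$duration, config$rate)
    ang <- list(WFE = gen(1), WAA = gen(0.5),
                EPS = gen(config$elbow_scale), EFE = gen(config$elbow_scale))
    upper_theta <- gen(config$upperarm_scale)
    streams <- .compose_recording_streams(ang, upper_theta, config$rate)
    draft <- tremor_recording(streams, label, id = id, subject = subject,
                              angles = c(list(time_s = streams$hand$time_s), ang))
    attr(draft, "upper_theta") <- upper_theta
    rec <- calibrate_subclinical(draft, rating_model, config$rating_target,
                                 preprocess_config(rate = config$rate))
    if (config$dropout_fraction > 0) {
      rec$streams <- lapply(rec$streams, apply_dropout,
                            fraction = config$dropout_fraction)
    }
    rec
  })
}

#' Simulate a labelled dataset
#'
#' @param n_per_class named counts `c(normal =, PD =, ET =)`, or `NULL`
#'   with `preset = "paper"` for the study composition (122 normal, 83 PD,
#'   30 ET readings).
#' @param preset signal-model preset: `"separable"`, `"overlapping"`,
#'   `"null"` or `"paper"` (separable models, study counts).
#' @param config a [sim_config()].
#' @param seed master seed; every recording derives its own sub-seed.
#' @return List of [tremor_recording()] objects; subjects contribute up to
#'   two recordings each.
#' @export
simulate_dataset <- function(n_per_class = c(normal = 10, PD = 10, ET = 10),
                             preset = c("separable", "overlapping", "null", "paper"),
                             config = sim_config(), seed = 1) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    n_per_class <- c(normal = 122, PD = 83, ET = 30)
    model_preset <- "separable"
  } else model_preset <- preset
  if (any(n_per_class <= 0)) stop("class counts must be positive")
  classes <- names(n_per_class)
  recs <- list()
  with_seed(seed, {
    for (cl in classes) {
      model <- class_signal_model(cl, preset = model_preset)
      made <- 0L; subj_i <- 0L
      while (made < n_per_class[[cl]]) {
        subj_i <- subj_i + 1L
        subject <- sprintf("%s_s%03d", cl, subj_i)
        n_read <- if (stats::runif(1) < config$two_reading_frac) 2L else 1L
        n_read <- min(n_read, n_per_class[[cl]] - made)
        for (r in seq_len(n_read)) {
          made <- made + 1L
          id <- sprintf("%s_r%03d", cl, made)
          rec_seed <- sample.int(.Machine$integer.max - 1L, 1L)
          recs[[id]] <- simulate_recording(cl, model, config, seed = rec_seed,
                                           id = id, subject = subject)
        }
      }
    }
  })
  recs
}

#' Write a dataset manifest
#'
#' JSON manifest of ids, subjects, labels and calibrated ratings so a
#' simulated experiment is exactly re-runnable and auditable.
#'
#' @param recordings list of [tremor_recording()]s.
#' @param path output JSON path.
#' @param seed the master seed used (recorded verbatim).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(recordings, path, seed = NULL) {
  manifest <- list(
    seed = seed,
    n = length(recordings),
    recordings = lapply(unname(recordings), function(r)
      list(id = r$id, subject = r$subject, label = r$label,
           class = class_name(r$label), rating = r$rating,
           subclinical = is_subclinical(r$rating))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
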