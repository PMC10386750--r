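# Chest-motion model and slow-time phase synthesis.
#
# A subject's chest surface sits at baseline distance d0 from the radar and
# oscillates with respiration (amplitude mb, frequency fb) and heartbeat
# (amplitude mh, frequency fh):
#   d(t) = d0 + mb sin(2 pi fb t) + mh sin(2 pi fh t)
# The displacement from baseline modulates the echo phase as
#   theta = 4 pi x / lambda.
# The simulator composes the two, adds Gaussian phase noise and an optional
# gross body-motion transient, and returns a uniformly sampled phase series.

SPEED_OF_LIGHT <- 299792458

#' Two-sinusoid chest displacement model
#'
#' Parameters of the chest-surface displacement induced by respiration and
#' heartbeat. Defaults sit in the middle of the physiological bands
#' (respiration 0.1--0.3 Hz at 4--12 mm, heartbeat 1--2 Hz at 0.2--0.5 mm).
#'
#' @param d0 Baseline chest--radar distance in metres (> 0).
#' @param mb Respiration displacement amplitude in metres (>= 0).
#' @param mh Heartbeat displacement amplitude in metres (>= 0).
#' @param fb Respiration frequency in Hz (> 0).
#' @param fh Heartbeat frequency in Hz (> 0).
#' @return An object of class `chest_motion_model`.
#' @export
#' @examples
#' m <- chest_motion_model(fb = 0.25, fh = 1.2)
#' chest_displacement(m, c(0, 0.5, 1))
chest_motion_model <- function(d0 = 0.6, mb = 8e-3, mh = 0.35e-3,
                               fb = 0.2, fh = 1.2) {
  vals <- c(d0 = d0, mb = mb, mh = mh, fb = fb, fh = fh)
  if (!all(is.finite(vals))) {
    stop("invalid chest motion model: all parameters must be finite numbers")
  }
  if (d0 <= 0) stop("invalid chest motion model: d0 must be > 0")
  if (mb < 0 || mh < 0) {
    stop("invalid chest motion model: amplitudes mb, mh must be >= 0")
  }
  if (fb <= 0 || fh <= 0) {
    stop("invalid chest motion model: frequencies fb, fh must be > 0")
  }
  structure(list(d0 = d0, mb = mb, mh = mh, fb = fb, fh = fh),
            class = "chest_motion_model")
}

#' @export
print.chest_motion_model <- function(x, ...) {
  cat("Chest motion model\n")
  cat(sprintf("  baseline distance d0: %.3f m\n", x$d0))
  cat(sprintf("  respiration: %.1f mm at %.2f Hz\n", 1e3 * x$mb, x$fb))
  cat(sprintf("  heartbeat:   %.2f mm at %.2f Hz\n", 1e3 * x$mh, x$fh))
  invisible(x)
}

#' UWB radar and slow-time sampling configuration
#'
#' @param carrier_frequency Carrier frequency in Hz; the UWB band considered
#'   here spans 6.5--8.1 GHz, default mid-band 7.3 GHz. The wavelength is
#'   derived as `lambda = c / carrier_frequency`.
#' @param sampling_rate Slow-time sampling rate in Hz (default 20, giving
#'   Nyquist margin for heartbeats up to 2 Hz).
#' @param duration Duration of the synthesized series in seconds.
#' @param noise_sd Standard deviation of additive Gaussian phase noise, in
#'   radians.
#' @param motion_transient Optional gross body-motion pulse: a list with
#'   elements `start` (s), `duration` (s) and `amplitude` (m). Body motion is
#'   at centimetre level or above, so the conventional default amplitude when
#'   one is requested is 0.02 m.
#' @return An object of class `radar_config` with derived field `wavelength`.
#' @export
radar_config <- function(carrier_frequency = 7.3e9, sampling_rate = 20,
                         duration = 60, noise_sd = 0,
                         motion_transient = NULL) {
  vals <- c(carrier_frequency, sampling_rate, duration, noise_sd)
  if (!all(is.finite(vals))) stop("invalid radar config: non-finite field")
  if (carrier_frequency <= 0) {
    stop("invalid radar config: carrier_frequency must be > 0")
  }
  if (sampling_rate <= 0) stop("invalid radar config: sampling_rate must be > 0")
  if (duration <= 0) stop("invalid radar config: duration must be > 0")
  if (noise_sd < 0) stop("invalid radar config: noise_sd must be >= 0")
  if (!is.null(motion_transient)) {
    req <- c("start", "duration", "amplitude")
    if (!is.list(motion_transient) || !all(req %in% names(motion_transient))) {
      stop("invalid radar config: motion_transient needs start, duration, amplitude")
    }
    if (motion_transient$duration <= 0 || motion_transient$start < 0) {
      stop("invalid radar config: motion_transient timing must be positive")
    }
  }
  structure(list(carrier_frequency = carrier_frequency,
                 wavelength = SPEED_OF_LIGHT / carrier_frequency,
                 sampling_rate = sampling_rate,
                 duration = duration,
                 noise_sd = noise_sd,
                 motion_transient = motion_transient),
            class = "radar_config")
}

#' Chest displacement at given times
#'
#' Evaluates `d(t) = d0 + mb sin(2 pi fb t) + mh sin(2 pi fh t)`.
#'
#' @param model A [chest_motion_model()].
#' @param times Numeric vector of times in seconds (finite).
#' @return Displacement in metres, one value per time.
#' @export
chest_displacement <- function(model, times) {
  stopifnot(inherits(model, "chest_motion_model"))
  if (!is.numeric(times) || anyNA(times) || any(!is.finite(times))) {
    stop("times must be finite numbers")
  }
  model$d0 + model$mb * sin(2 * pi * model$fb * times) +
    model$mh * sin(2 * pi * model$fh * times)
}

#' Phase modulation of a displacement series
#'
#' Converts displacement from baseline into echo phase, `theta = 4 pi x /
#' lambda`. The relation is linear in `x`; phase is kept unwrapped.
#'
#' @param displacement_from_baseline Displacement in metres.
#' @param wavelength Carrier wavelength in metres (> 0).
#' @return Phase in radians.
#' @export
phase_modulation <- function(displacement_from_baseline, wavelength) {
  if (!is.numeric(wavelength) || length(wavelength) != 1 ||
      !is.finite(wavelength) || wavelength <= 0) {
    stop("invalid config: wavelength must be a single positive number")
  }
  4 * pi * displacement_from_baseline / wavelength
}

# Raised-cosine displacement pulse for a gross body-motion transient.
transient_displacement <- function(times, transient) {
  if (is.null(transient)) return(numeric(length(times)))
  t0 <- transient$start
  dur <- transient$duration
  inside <- times >= t0 & times <= t0 + dur
  out <- numeric(length(times))
  out[inside] <- transient$amplitude * 0.5 *
    (1 - cos(2 * pi * (times[inside] - t0) / dur))
  out
}

#' Synthesize a slow-time phase series
#'
#' Composes [chest_displacement()] and [phase_modulation()], then adds
#' Gaussian phase noise and, if configured, a raised-cosine body-motion
#' transient. Reproducible under a fixed seed.
#'
#' @param model A [chest_motion_model()].
#' @param config A [radar_config()]; its sampling rate must exceed twice the
#'   larger of the model's two frequencies.
#' @param seed Optional integer seed for the noise stream.
#' @return An object of class `phase_series`: list with `values` (radians),
#'   `time` (s), `fs` (Hz) and `wavelength` (m).
#' @export
synthesize_phase_series <- function(model, config, seed = NULL) {
  stopifnot(inherits(model, "chest_motion_model"),
            inherits(config, "radar_config"))
  if (config$sampling_rate <= 2 * max(model$fb, model$fh)) {
    stop(sprintf(
      "sampling error: fs = %g Hz violates Nyquist for max frequency %g Hz",
      config$sampling_rate, max(model$fb, model$fh)))
  }
  n <- round(config$duration * config$sampling_rate)
  times <- (seq_len(n) - 1) / config$sampling_rate
  x <- chest_displacement(model, times) - model$d0 +
    transient_displacement(times, config$motion_transient)
  phase <- phase_modulation(x, config$wavelength)
  if (config$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    phase <- phase + stats::rnorm(n, 0, config$noise_sd)
  }
  structure(list(values = phase, time = times, fs = config$sampling_rate,
                 wavelength = config$wavelength),
            class = "phase_series")
}

#' Construct a phase series from raw samples
#'
#' @param values Phase samples in radians (finite).
#' @param fs Sampling rate in Hz.
#' @param wavelength Carrier wavelength in metres (optional; NA when unknown).
#' @return A `phase_series` object.
#' @export
phase_series <- function(values, fs, wavelength = NA_real_) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("phase series values must be finite")
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  structure(list(values = as.numeric(values),
                 time = (seq_along(values) - 1) / fs,
                 fs = fs, wavelength = wavelength),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("Phase series: %d samples at %g Hz (%.1f s)\n",
              length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}
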