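# Vitals extraction from a slow-time phase series: band-restricted spectral
# peak estimation for respiration/heart rate, band-limited motion energy,
# four-level motion-status classification, and time-of-flight distance.

#' Motion-energy configuration
#'
#' Band of interest for motion energy and the three ordered thresholds that
#' partition energy into four motion statuses.
#'
#' @param band Frequency band of interest `(low, high)` in Hz; defaults to
#'   0.05--4 Hz, covering respiration, heartbeat and gross motion.
#' @param thresholds Increasing numeric vector `(e1, e2, e3)` of energy
#'   thresholds (all >= 0).
#' @return An object of class `motion_energy_config`.
#' @export
motion_energy_config <- function(band = c(0.05, 4), thresholds) {
  if (length(band) != 2 || any(!is.finite(band)) || band[1] < 0 ||
      band[1] >= band[2]) {
    stop("invalid config: band must satisfy 0 <= low < high")
  }
  if (length(thresholds) != 3 || any(!is.finite(thresholds)) ||
      any(thresholds < 0) || any(diff(thresholds) <= 0)) {
    stop("invalid config: thresholds must satisfy 0 <= e1 < e2 < e3")
  }
  structure(list(band = as.numeric(band),
                 thresholds = as.numeric(thresholds)),
            class = "motion_energy_config")
}

# Magnitude spectrum of a detrended, Hann-windowed, zero-padded series.
# Returns list(freq, mag) on the one-sided grid.
windowed_spectrum <- function(values, fs) {
  n <- length(values)
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), values)
  detrended <- fit$residuals
  hann <- 0.5 * (1 - cos(2 * pi * (t - 1) / (n - 1)))
  w <- detrended * hann
  nfft <- 2^ceiling(log2(n))
  w <- c(w, numeric(nfft - n))
  mag <- Mod(stats::fft(w))[seq_len(nfft %/% 2 + 1)]
  list(freq = (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft, mag = mag)
}

band_peak_frequency <- function(series, band, what) {
  width <- band[2] - band[1]
  need <- ceiling(2 * series$fs / width)
  if (length(series$values) < need) {
    stop(sprintf(
      "insufficient data: %s band (%.2f-%.2f Hz) needs >= %d samples at fs = %g Hz, got %d",
      what, band[1], band[2], need, series$fs, length(series$values)))
  }
  sp <- windowed_spectrum(series$values, series$fs)
  in_band <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(in_band)) stop("invalid config: band contains no spectral bins")
  f <- sp$freq[in_band]
  m <- sp$mag[in_band]
  f[which.max(m)]  # which.max returns the first max: ties go to the lower bin
}

#' Estimate respiration and heart rate from a phase series
#'
#' For each band the series is detrended, Hann-windowed and zero-padded to
#' the next power of two; the rate is 60 times the frequency of the largest
#' magnitude bin inside the band (ties broken toward the lower frequency).
#' Estimates are invariant to constant phase offsets.
#'
#' @param series A `phase_series`.
#' @param respiration_band Respiration band in Hz, default `c(0.1, 0.3)`.
#' @param heart_band Heart band in Hz, default `c(1, 2)`.
#' @return Named numeric vector `c(respiration_rate, heart_rate)` in
#'   breaths/min and BPM.
#' @export
#' @examples
#' m <- chest_motion_model(fb = 0.25, fh = 1.5)
#' s <- synthesize_phase_series(m, radar_config())
#' estimate_rates(s)
estimate_rates <- function(series, respiration_band = c(0.1, 0.3),
                           heart_band = c(1, 2)) {
  stopifnot(inherits(series, "phase_series"))
  rr <- 60 * band_peak_frequency(series, respiration_band, "respiration")
  hr <- 60 * band_peak_frequency(series, heart_band, "heart")
  c(respiration_rate = rr, heart_rate = hr)
}

#' Band-limited motion energy of a phase series
#'
#' Energy is the maximum DFT modulus over the band of interest multiplied by
#' the band width. The mean is removed first (so a constant series has zero
#' energy) but no window is applied, keeping the statistic exactly linear in
#' the signal amplitude.
#'
#' @param series A non-empty `phase_series`.
#' @param config A [motion_energy_config()].
#' @return Nonnegative scalar energy (rad * Hz).
#' @export
motion_energy <- function(series, config) {
  stopifnot(inherits(series, "phase_series"),
            inherits(config, "motion_energy_config"))
  n <- length(series$values)
  if (n == 0) stop("insufficient data: empty series")
  centred <- series$values - mean(series$values)
  mag <- Mod(stats::fft(centred))
  freq <- (seq_len(n) - 1) * series$fs / n
  in_band <- freq >= config$band[1] & freq <= config$band[2]
  if (!any(in_band)) {
    stop("invalid config: band of interest contains no spectral bins")
  }
  max(mag[in_band]) * (config$band[2] - config$band[1])
}

MOTION_STATUS_LEVELS <- c("stillness", "relative_stillness", "motion",
                          "continuous_motion")

#' Classify motion status from an energy value
#'
#' Thresholds are half-open and lower-inclusive on the upper side: energy
#' exactly equal to a threshold maps to the higher-motion class.
#'
#' @param energy Nonnegative energy value (vectorized).
#' @param config A [motion_energy_config()].
#' @return Ordered factor over stillness, relative_stillness, motion,
#'   continuous_motion.
#' @export
classify_motion_status <- function(energy, config) {
  stopifnot(inherits(config, "motion_energy_config"))
  if (any(!is.finite(energy)) || any(energy < 0)) {
    stop("energy must be finite and >= 0")
  }
  cut(energy, breaks = c(-Inf, config$thresholds, Inf),
      labels = MOTION_STATUS_LEVELS, right = FALSE, ordered_result = TRUE)
}

#' Calibrate motion-energy thresholds from still-subject simulations
#'
#' Simulates still subjects (respiration/heartbeat parameters drawn from
#' their physiological ranges plus phase noise), sets `e1` to the 95th
#' percentile of their energies and spaces the remaining thresholds
#' geometrically: `e2 = 2 e1`, `e3 = 4 e1`.
#'
#' @param n_sims Number of still-subject simulations.
#' @param band Band of interest passed through to the returned config.
#' @param noise_sd Phase noise used in the simulations (radians).
#' @param duration,fs Simulation length (s) and sampling rate (Hz).
#' @param seed Integer seed.
#' @return A [motion_energy_config()].
#' @export
calibrate_motion_thresholds <- function(n_sims = 50, band = c(0.05, 4),
                                        noise_sd = 0.05, duration = 60,
                                        fs = 20, seed = 1) {
  set.seed(seed)
  cfg_probe <- motion_energy_config(band, thresholds = c(1, 2, 3))
  energies <- vapply(seq_len(n_sims), function(i) {
    m <- chest_motion_model(mb = stats::runif(1, 4e-3, 12e-3),
                            mh = stats::runif(1, 0.2e-3, 0.5e-3),
                            fb = stats::runif(1, 0.1, 0.3),
                            fh = stats::runif(1, 1, 2))
    cfg <- radar_config(sampling_rate = fs, duration = duration,
                        noise_sd = noise_sd)
    s <- synthesize_phase_series(m, cfg, seed = sample.int(2^30, 1))
    motion_energy(s, cfg_probe)
  }, numeric(1))
  e1 <- as.numeric(stats::quantile(energies, 0.95))
  motion_energy_config(band, thresholds = c(e1, 2 * e1, 4 * e1))
}

#' Convert a round-trip delay into target distance
#'
#' `R = c tD / 2` with `c` the speed of light in vacuum.
#'
#' @param tD Round-trip delay in seconds (>= 0, vectorized).
#' @return Distance in metres.
#' @export
delay_to_distance <- function(tD) {
  if (!is.numeric(tD) || any(!is.finite(tD))) stop("invalid input: delay must be finite")
  if (any(tD < 0)) stop("invalid input: negative delay")
  SPEED_OF_LIGHT * tD / 2
}

#' Full vitals estimate from a phase series
#'
#' Convenience wrapper combining [estimate_rates()], [motion_energy()] and
#' [classify_motion_status()].
#'
#' @param series A `phase_series`.
#' @param config A [motion_energy_config()].
#' @param respiration_band,heart_band Bands in Hz.
#' @param delay Optional round-trip delay in seconds for the distance field.
#' @return List of class `vitals_estimate`.
#' @export
vitals_estimate <- function(series, config,
                            respiration_band = c(0.1, 0.3),
                            heart_band = c(1, 2), delay = NULL) {
  rates <- estimate_rates(series, respiration_band, heart_band)
  energy <- motion_energy(series, config)
  structure(list(
    respiration_rate = unname(rates["respiration_rate"]),
    heart_rate = unname(rates["heart_rate"]),
    motion_energy = energy,
    motion_status = as.character(classify_motion_status(energy, config)),
    distance = if (is.null(delay)) NA_real_ else delay_to_distance(delay)
  ), class = "vitals_estimate")
}
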