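test_that("rate estimation recovers single tones within one FFT bin", {
  # single respiration tone at 0.25 Hz -> 15 breaths/min
  m <- chest_motion_model(fb = 0.25, mh = 0)
  s <- synthesize_phase_series(m, radar_config(noise_sd = 0))
  nfft <- 2^ceiling(log2(length(s$values)))
  bin_bpm <- 60 * s$fs / nfft
  r <- estimate_rates(s)
  expect_lt(abs(r[["respiration_rate"]] - 15), bin_bpm + 1e-9)

  # joint tones (0.2, 1.5) -> (12, 90)
  m2 <- chest_motion_model(fb = 0.2, fh = 1.5)
  s2 <- synthesize_phase_series(m2, radar_config(noise_sd = 0))
  r2 <- estimate_rates(s2)
  expect_lt(abs(r2[["respiration_rate"]] - 12), bin_bpm + 1e-9)
  expect_lt(abs(r2[["heart_rate"]] - 90), bin_bpm + 1e-9)
})

test_that("rates drawn across physiological bands land inside them", {
  set.seed(9)
  for (r in 1:5) {
    m <- chest_motion_model(fb = runif(1, 0.1, 0.3), fh = runif(1, 1, 2))
    s <- synthesize_phase_series(m, radar_config(noise_sd = 0.02),
                                 seed = 100 + r)
    est <- estimate_rates(s)
    expect_gte(est[["respiration_rate"]], 60 * 0.1)
    expect_lte(est[["respiration_rate"]], 60 * 0.3)
    expect_gte(est[["heart_rate"]], 60 * 1)
    expect_lte(est[["heart_rate"]], 60 * 2)
  }
})

test_that("rate estimation is offset-invariant and guards short series", {
  m <- chest_motion_model(fb = 0.2, fh = 1.5)
  s <- synthesize_phase_series(m, radar_config(noise_sd = 0))
  shifted <- phase_series(s$values + 17.3, s$fs)
  expect_equal(estimate_rates(shifted), estimate_rates(s))

  short <- phase_series(rnorm(50), fs = 20)
  expect_error(estimate_rates(short), "insufficient data")
})

test_that("motion energy matches a direct DFT oracle and is linear", {
  cfg <- motion_energy_config(band = c(0.05, 4), thresholds = c(1, 2, 3))
  zero <- phase_series(rep(0, 128), fs = 20)
  expect_equal(motion_energy(zero, cfg), 0)

  set.seed(3)
  s <- phase_series(rnorm(200), fs = 20)
  s2 <- phase_series(2 * s$values, fs = 20)
  expect_equal(motion_energy(s2, cfg), 2 * motion_energy(s, cfg))

  # unit-amplitude in-band sinusoid: energy = max band modulus x band width,
  # cross-checked with an independently coded direct DFT
  n <- 128
  fs <- 16
  x <- sin(2 * pi * 2 * (0:(n - 1)) / fs)  # 2 Hz -> bin 16
  tone <- phase_series(x, fs = fs)
  centred <- x - mean(x)
  freq <- (0:(n - 1)) * fs / n
  in_band <- freq >= 0.05 & freq <= 4
  oracle <- max(vapply(which(in_band) - 1,
                       function(k) direct_dft_mag(centred, k), numeric(1)))
  expect_equal(motion_energy(tone, cfg), oracle * (4 - 0.05),
               tolerance = 1e-10)

  bad <- motion_energy_config(band = c(9, 9.5), thresholds = c(1, 2, 3))
  expect_error(motion_energy(phase_series(rnorm(16), 4), bad),
               "invalid config")
})

test_that("motion status classification is the documented step function", {
  cfg <- motion_energy_config(thresholds = c(1, 2, 3))
  expect_equal(as.character(classify_motion_status(0, cfg)), "stillness")
  expect_equal(as.character(classify_motion_status(2, cfg)), "motion")

  # exhaustive sweep against a brute-force comparison table
  energies <- seq(0, 4, by = 0.1)
  got <- as.character(classify_motion_status(energies, cfg))
  want <- ifelse(energies < 1, "stillness",
          ifelse(energies < 2, "relative_stillness",
          ifelse(energies < 3, "motion", "continuous_motion")))
  expect_equal(got, want)

  # monotonicity: larger energy never maps to a stiller status
  codes <- as.integer(classify_motion_status(sort(runif(50, 0, 5)), cfg))
  expect_true(all(diff(codes) >= 0))
})

test_that("a motion transient raises energy above the still baseline", {
  m <- chest_motion_model()
  cfg_me <- motion_energy_config(thresholds = c(1, 2, 3))
  still <- synthesize_phase_series(m, radar_config(noise_sd = 0.01), seed = 4)
  moving <- synthesize_phase_series(
    m, radar_config(noise_sd = 0.01, motion_transient = list(
      start = 20, duration = 3, amplitude = 0.02)), seed = 4)
  expect_gt(motion_energy(moving, cfg_me), motion_energy(still, cfg_me))
})

test_that("threshold calibration produces ordered thresholds that call still subjects still", {
  cfg <- calibrate_motion_thresholds(n_sims = 20, seed = 2)
  expect_true(all(diff(cfg$thresholds) > 0))
  m <- chest_motion_model()
  s <- synthesize_phase_series(m, radar_config(noise_sd = 0.05), seed = 10)
  status <- classify_motion_status(motion_energy(s, cfg), cfg)
  expect_true(as.character(status) %in% c("stillness", "relative_stillness"))
})

test_that("delay-to-distance is c t / 2", {
  expect_equal(delay_to_distance(0), 0)
  expect_equal(delay_to_distance(10e-9), 299792458 * 10e-9 / 2)
  # algebraic inverse round trip at R = 1.5 m
  expect_equal(delay_to_distance(2 * 1.5 / 299792458), 1.5)
  expect_error(delay_to_distance(-1e-9), "negative delay")
})

test_that("vitals_estimate bundles the extraction outputs", {
  m <- chest_motion_model(fb = 0.2, fh = 1.5)
  s <- synthesize_phase_series(m, radar_config(noise_sd = 0))
  cfg <- motion_energy_config(thresholds = c(1e6, 2e6, 4e6))
  v <- vitals_estimate(s, cfg, delay = 4e-9)
  expect_s3_class(v, "vitals_estimate")
  expect_equal(v$distance, delay_to_distance(4e-9))
  expect_true(v$motion_status %in% c("stillness", "relative_stillness",
                                     "motion", "continuous_motion"))
})
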