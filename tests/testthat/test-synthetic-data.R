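test_that("zero targets calibrate to zero loadings and independence", {
  tau0 <- c(weight = 0, motion_status = 0)
  cal <- calibrate_dependence(target_tau = tau0, n_pilot = 2000, seed = 5)
  expect_equal(unname(cal$loading_weights), rep(0, 8))
  expect_true(all(abs(cal$achieved_tau) < 0.02 + 0.03))  # pure noise at n=2000
  df <- generate_correction_dataset(2000, cal, seed = 6)
  ae <- abs(df$radar_hr - df$oximeter_hr)
  expect_lt(abs(kendall_tau_b(df$weight, ae)), 0.05)
})

test_that("a single weight loading hits its published target", {
  cal <- calibrate_dependence(target_tau = c(weight = -0.274),
                              n_pilot = 10400, seed = 8)
  expect_lt(abs(cal$achieved_tau[["weight"]] - (-0.274)), 0.02)
  # Gaussian-copula closed form for the continuous, un-tied factor
  rho <- latent_correlation(cal, "weight")
  expect_lt(abs((2 / pi) * asin(rho) - (-0.274)), 0.03)
})

test_that("the default calibration matches all published coefficients", {
  cal <- calibrate_dependence(seed = 1)
  expect_true(all(abs(cal$achieved_tau - cal$target_tau) <= 0.02))
  # signs of loadings track signs of targets
  expect_equal(sign(cal$loading_weights), sign(cal$target_tau))
  # continuous factors obey tau ~= (2/pi) asin(rho)
  for (f in c("weight", "height", "distance")) {
    rho <- latent_correlation(cal, f)
    expect_lt(abs((2 / pi) * asin(rho) - cal$target_tau[[f]]), 0.03)
  }
})

test_that("generated datasets reproduce the dependence and error scale", {
  cal <- calibrate_dependence(seed = 1)
  df <- generate_correction_dataset(10400, cal, seed = 2)
  expect_equal(nrow(df), 10400)
  ae <- abs(df$radar_hr - df$oximeter_hr)
  expect_lt(abs(mean(ae) - 21.5), 2)
  for (f in names(cal$target_tau)) {
    expect_lt(abs(kendall_tau_b(df[[f]], ae) - cal$target_tau[[f]]), 0.03)
  }
  expect_true(all(df$oximeter_hr >= 30 & df$oximeter_hr <= 220))
  expect_true(all(df$radar_hr >= 30 & df$radar_hr <= 220))
  # determinism
  df2 <- generate_correction_dataset(10400, cal, seed = 2)
  expect_identical(df, df2)
})

test_that("degenerate calibration yields a constant positive bias", {
  cal <- calibrate_dependence(target_tau = c(weight = 0), n_pilot = 500,
                              seed = 3, residual_sd = 0)
  df <- generate_correction_dataset(200, cal, seed = 4)
  err <- df$radar_hr - df$oximeter_hr
  expect_equal(diff(range(err)), 0, tolerance = 1e-9)
  expect_gt(err[1], 0)
})

test_that("error given the nine features is nearly deterministic", {
  # identifiability: the signed error must be an (independently
  # reconstructable) deterministic monotone function of the observed
  # factors plus a residual of roughly residual_sd BPM
  cal <- calibrate_dependence(seed = 1, residual_sd = 2)
  df <- generate_correction_dataset(4000, cal, seed = 5)
  err <- df$radar_hr - df$oximeter_hr

  # reconstruct the factor scores from the observed values alone, using
  # truncated-normal conditional means computed here, not package internals
  trunc_mean <- function(p_lo, p_hi) {
    (dnorm(qnorm(p_lo)) - dnorm(qnorm(p_hi))) / (p_hi - p_lo)
  }
  score_of <- function(values, levels, probs) {
    cum <- cumsum(c(0, probs))
    s <- vapply(seq_along(levels), function(k) trunc_mean(cum[k], cum[k + 1]),
                numeric(1))
    s[match(values, levels)]
  }
  sc <- cbind(
    direction = score_of(df$direction, 0:5, rep(1 / 6, 6)),
    angle = score_of(df$angle, c(0, 35, 45, 90, 180), rep(1 / 5, 5)),
    gender = score_of(df$gender, 0:1, c(0.5, 0.5)),
    height = (df$height - 170) / 8,
    weight = (df$weight - 65) / 12,
    age = score_of(df$age, 18:65, rep(1 / 48, 48)),
    distance = qnorm((df$distance - 0.5) / 2.5),
    motion_status = score_of(df$motion_status, 0:3, rep(0.25, 4)))
  S_hat <- as.numeric(sc[, names(cal$loading_weights)] %*%
                        cal$loading_weights)
  err_hat <- cal$scale * log1p(exp(S_hat))
  resid <- err - err_hat
  # conditional spread is close to the configured residual (in BPM) and
  # far below the marginal error spread
  expect_lt(sd(resid), 2 * cal$residual_sd)
  expect_gt(sd(resid), 0.3 * cal$residual_sd)
  expect_lt(sd(resid), 0.5 * sd(err) + 2)
})

test_that("normal RR sequences have the stated mean, drift and determinism", {
  const <- generate_rr_sequence(100, normal_sd = 0, seed = 1)
  expect_equal(const$intervals, rep(900, 100))

  seq1 <- generate_rr_sequence(1600, normal_mean = 900, normal_sd = 40,
                               seed = 2)
  expect_lt(abs(mean(seq1$intervals) - 900), 3 * 40 / sqrt(1600) / sqrt(1 - 0.9))
  seq2 <- generate_rr_sequence(1600, seed = 2)
  expect_identical(seq1$intervals, seq2$intervals)
  # autocorrelated drift present
  expect_gt(cor(seq1$intervals[-1], seq1$intervals[-1600]), 0.5)

  expect_warning(generate_rr_sequence(50, normal_mean = 10, normal_sd = 200,
                                      seed = 3), "clipped")
})

test_that("abnormal segment insertion annotates non-overlapping segments", {
  base <- generate_rr_sequence(1600, seed = 10)
  expect_identical(insert_abnormal_segments(base, list()), base)

  means <- c(350, 315, 450, 350, 299.5, 502)
  seq_ab <- insert_abnormal_segments(
    base, lapply(means, function(m) list(mean_rr = m, length = NA)),
    seed = 11)
  segs <- seq_ab$segments
  expect_length(segs, 6)
  starts <- vapply(segs, function(s) s$i, numeric(1))
  ends <- vapply(segs, function(s) s$j, numeric(1))
  expect_true(all(starts >= 1024))
  expect_true(all(ends > starts))
  expect_true(all(ends <= 1600))
  expect_true(all(starts[-1] > ends[-6] + 1))  # >= 1 normal interval between
  for (k in seq_along(segs)) {
    realized <- mean(seq_ab$intervals[segs[[k]]$i:segs[[k]]$j])
    expect_lt(abs(realized - means[k]), 10)
  }
  # untouched intervals preserved
  touched <- unlist(lapply(segs, function(s) s$i:s$j))
  expect_identical(seq_ab$intervals[-touched], base$intervals[-touched])

  expect_error(
    insert_abnormal_segments(base, list(list(mean_rr = 300, length = 600)),
                             seed = 1),
    "placement error")
})

test_that("window labelling follows the last-interval rule", {
  plain <- generate_rr_sequence(1024, seed = 1)
  lab0 <- label_windows(plain)
  expect_equal(nrow(lab0), 1)
  expect_false(lab0$is_abnormal)

  base <- generate_rr_sequence(1600, seed = 2)
  seg <- rr_sequence(base$intervals,
                     list(list(i = 1100, j = 1150, mean_rr = 350)))
  lab <- label_windows(seg)
  expect_equal(nrow(lab), 577)  # n - window + 1
  expect_true(all(lab$is_abnormal[lab$end_index >= 1100 &
                                  lab$end_index <= 1150]))
  expect_false(any(lab$is_abnormal[lab$end_index < 1100 |
                                   lab$end_index > 1150]))

  expect_error(label_windows(generate_rr_sequence(500, seed = 3)),
               "insufficient data")
})

test_that("detector corpora are balanced, labelled and deterministic", {
  c1 <- make_detector_corpus(n_seq = 3, seed = 6)
  c2 <- make_detector_corpus(n_seq = 3, seed = 6)
  expect_identical(c1, c2)
  expect_equal(ncol(c1$windows), 1024)
  expect_equal(sum(c1$labels == 0), sum(c1$labels == 1))
  # abnormal windows end in intervals far below normal on average
  last <- c1$windows[, 1024]
  expect_lt(mean(last[c1$labels == 1]), mean(last[c1$labels == 0]) - 200)
})
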