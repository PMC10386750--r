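test_that("cross-entropy matches hand values and is label-swap invariant", {
  y <- c(1, 0, 1)
  expect_lt(cross_entropy_loss(y, y), 1e-10)
  expect_equal(cross_entropy_loss(c(0.5, 0.5), c(1, 0)), log(2))
  set.seed(1)
  p <- runif(20, 0.01, 0.99)
  lab <- rbinom(20, 1, 0.5)
  expect_equal(cross_entropy_loss(p, lab),
               cross_entropy_loss(1 - p, 1 - lab))
  expect_gte(cross_entropy_loss(p, lab), 0)
  expect_error(cross_entropy_loss(p, lab[-1]), "shape error")
})

test_that("Adam reproduces the hand-iterated update", {
  s0 <- adam_step(adam_state(0, alpha = 0.1), 0)
  expect_equal(s0$theta, 0)  # cold start, zero gradient

  s1 <- adam_step(adam_state(0, alpha = 0.1, eps = 0), 1)
  expect_equal(s1$theta, -0.1)  # mhat = vhat = 1 at t = 1
  expect_equal(s1$t, 1L)

  # per-step update bounded by ~alpha under a constant gradient
  s <- adam_state(0, alpha = 0.05, eps = 1e-8)
  prev <- 0
  for (i in 1:50) {
    s <- adam_step(s, 3)
    expect_lte(abs(s$theta - prev), 0.05 * 1.01)
    prev <- s$theta
  }

  expect_error(adam_step(adam_state(0), Inf), "numerical error")
})

test_that("constant-level windows are perfectly separated", {
  const <- list(windows = rbind(matrix(900, 30, 64), matrix(350, 30, 64)),
                labels = rep(c(0L, 1L), each = 30))
  m <- train_detector(const$windows, const$labels,
                      small_detector_config(epochs = 5))
  expect_equal(tail(m$log$val_accuracy, 1), 1)
  expect_false(any(sliding_window_detect(m, rr_sequence(rep(900, 200)))$flags$flag))
})

test_that("a separable trailing-run corpus trains to perfect validation accuracy", {
  corp <- small_corpus(n_each = 40)
  cfg <- small_detector_config(epochs = 20, alpha = 3e-3,
                               conv_channels = c(8, 16))
  model <- train_detector(corp$windows, corp$labels, cfg)
  expect_equal(tail(model$log$val_accuracy, 1), 1)

  # determinism: same seed, same final accuracy and parameters
  model2 <- train_detector(corp$windows, corp$labels, cfg)
  expect_identical(model$params, model2$params)
  expect_identical(tail(model$log$val_accuracy, 1),
                   tail(model2$log$val_accuracy, 1))

  expect_error(train_detector(corp$windows, rep(1, nrow(corp$windows)),
                              small_detector_config()),
               "class-balance error")
})

test_that("sliding-window detection emits exactly n - window + 1 flags", {
  corp <- small_corpus(n_each = 40)
  model <- train_detector(corp$windows, corp$labels, small_detector_config())
  for (n in c(64, 100, 231)) {
    seq_n <- rr_sequence(rnorm(n, 900, 30))
    det <- sliding_window_detect(model, seq_n)
    expect_equal(nrow(det$flags), n - 64 + 1)
    expect_equal(det$flags$end_index, 64:n)
  }
  # all-normal constant sequence: no flags from the separable model
  det0 <- sliding_window_detect(model, rr_sequence(rep(900, 200)))
  expect_false(any(det0$flags$flag))
  expect_error(sliding_window_detect(model, rr_sequence(rep(900, 63))),
               "insufficient data")
})

test_that("latency value follows Definition-style index algebra", {
  mk_result <- function(flag_at, n = 200, window = 64, segments = list()) {
    flags <- data.frame(end_index = window:n, prob = 0, flag = FALSE)
    flags$flag[flags$end_index %in% flag_at] <- TRUE
    flags$prob[flags$flag] <- 1
    structure(list(flags = flags, segments = segments, window = window),
              class = "detection_result")
  }
  seg <- list(i = 100, j = 130, mean_rr = 350)

  r <- latency_k(mk_result(105), seg)
  expect_true(r$detected)
  expect_equal(r$k, 5)

  r0 <- latency_k(mk_result(100), seg)
  expect_equal(r0$k, 1)  # clamp: flag at the first abnormal interval

  r1 <- latency_k(mk_result(101), seg)
  expect_equal(r1$k, 1)  # e* - i = 1 also yields k = 1

  miss <- latency_k(mk_result(integer(0)), seg)
  expect_false(miss$detected)
  expect_true(is.na(miss$k))

  # flags before i are false alarms, not detections
  fa <- latency_k(mk_result(c(80, 90, 110)), seg)
  expect_equal(fa$k, 10)
  expect_equal(fa$false_alarms, 2)

  expect_error(latency_k(mk_result(105, n = 120), seg), "range error")
  expect_error(latency_k(mk_result(105), list(i = 30, j = 50)), "j > i")

  # brute-force scan oracle over random flag patterns
  set.seed(33)
  for (rep in 1:20) {
    flag_at <- sort(sample(64:200, sample(0:8, 1)))
    res <- mk_result(flag_at)
    got <- latency_k(res, seg)
    want <- brute_latency(res$flags, seg$i)
    if (is.na(want)) expect_false(got$detected) else expect_equal(got$k, want)
  }
})

test_that("lowering the decision threshold never increases latency", {
  corp <- small_corpus(n_each = 40)
  model <- train_detector(corp$windows, corp$labels, small_detector_config())
  set.seed(12)
  base <- rr_sequence(rnorm(300, 900, 30))
  seq_ab <- insert_abnormal_segments(
    base, list(list(mean_rr = 350, length = 20)), min_start = 64, seed = 13)
  seg <- seq_ab$segments[[1]]
  ks <- c()
  for (th in c(0.9, 0.5, 0.1)) {
    det <- sliding_window_detect(model, seq_ab, threshold = th)
    lat <- latency_k(det, seg)
    ks <- c(ks, if (lat$detected) lat$k else Inf)
  }
  expect_true(all(diff(ks) <= 0))
})

test_that("the latency experiment summarises per-segment results", {
  corp <- small_corpus(n_each = 40)
  model <- train_detector(corp$windows, corp$labels, small_detector_config())
  set.seed(14)
  base <- rr_sequence(rnorm(400, 900, 30))
  seq_ab <- insert_abnormal_segments(
    base, list(list(mean_rr = 350, length = 20),
               list(mean_rr = 300, length = 25)),
    min_start = 64, seed = 15)
  lat <- evaluate_latency_experiment(model, seq_ab, max_k = 10)
  expect_equal(nrow(lat$table), 2)
  expect_true(all(lat$table$result == "success"))
  expect_lte(lat$max_latency, 10)
  # realized means recomputed from the emitted sequence
  expect_lt(abs(lat$table$average_rr_ms[1] - 350), 10)

  expect_error(evaluate_latency_experiment(model, base), "no annotated")
})
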