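# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain R loops and direct formula evaluation.

# O(n^2) pair-counting Kendall tau-b.
brute_tau_b <- function(a, b) {
  n <- length(a)
  C <- D <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- a[i] - a[j]
      dy <- b[i] - b[j]
      if (dx == 0) tx <- tx + 1
      if (dy == 0) ty <- ty + 1
      if (dx != 0 && dy != 0) {
        if (sign(dx) == sign(dy)) C <- C + 1 else D <- D + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Direct DFT magnitude at bin k (0-based), naive O(n) sum.
direct_dft_mag <- function(x, k) {
  n <- length(x)
  t <- 0:(n - 1)
  re <- sum(x * cos(-2 * pi * k * t / n))
  im <- sum(x * sin(-2 * pi * k * t / n))
  sqrt(re^2 + im^2)
}

# Naive error-metric loops.
naive_metrics <- function(y, yhat) {
  n <- length(y)
  mae <- 0
  mse <- 0
  mre <- 0
  for (i in 1:n) {
    mae <- mae + abs(y[i] - yhat[i]) / n
    mse <- mse + (y[i] - yhat[i])^2 / n
    mre <- mre + abs(y[i] - yhat[i]) / y[i] / n
  }
  c(mae = mae, mse = mse, mre = mre)
}

# Brute-force latency scan: first flagged end index >= i, clamped to >= 1.
brute_latency <- function(flag_df, i) {
  for (r in seq_len(nrow(flag_df))) {
    if (flag_df$flag[r] && flag_df$end_index[r] >= i) {
      return(max(flag_df$end_index[r] - i, 1))
    }
  }
  NA_integer_
}

# Small detector geometry for fast tests (window 64).
small_detector_config <- function(...) {
  args <- utils::modifyList(
    list(window = 64, conv_channels = c(4, 8), kernel_sizes = c(5, 3),
         pool_sizes = c(2, 2), fc_widths = c(16, 8), epochs = 10,
         batch_size = 16, seed = 7),
    list(...))
  do.call(detector_net_config, args)
}

# Tiny separable window corpus for the small geometry: normal windows sit
# at 900 ms, abnormal ones end in a run of short intervals.
small_corpus <- function(n_each = 40, window = 64, seed = 5) {
  set.seed(seed)
  normal <- matrix(rnorm(n_each * window, 900, 30), n_each)
  abnormal <- matrix(rnorm(n_each * window, 900, 30), n_each)
  for (r in seq_len(n_each)) {
    tail_len <- sample(1:10, 1)
    abnormal[r, (window - tail_len + 1):window] <- rnorm(tail_len, 330, 10)
  }
  list(windows = rbind(normal, abnormal),
       labels = rep(c(0L, 1L), each = n_each))
}
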