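# Synthetic RR-interval sequences with inserted tachyarrhythmia-like
# abnormal segments, plus window labelling for detector training.

#' Construct an RR-interval sequence object
#'
#' @param intervals Positive RR intervals in milliseconds.
#' @param segments List of abnormal-segment annotations, each a list with
#'   1-based inclusive `i` (start), `j` (end) and `mean_rr` (ms).
#' @return Object of class `rr_sequence`.
#' @export
rr_sequence <- function(intervals, segments = list()) {
  if (length(intervals) < 1 || any(!is.finite(intervals)) ||
      any(intervals <= 0)) {
    stop("intervals must be positive and finite, length >= 1")
  }
  for (seg in segments) {
    if (!all(c("i", "j", "mean_rr") %in% names(seg))) {
      stop("each segment needs fields i, j, mean_rr")
    }
    if (seg$j <= seg$i || seg$i < 1 || seg$j > length(intervals)) {
      stop("segment must satisfy 1 <= i < j <= n")
    }
  }
  structure(list(intervals = as.numeric(intervals), segments = segments),
            class = "rr_sequence")
}

#' @export
print.rr_sequence <- function(x, ...) {
  cat(sprintf("RR sequence: %d intervals, mean %.0f ms, %d abnormal segment(s)\n",
              length(x$intervals), mean(x$intervals), length(x$segments)))
  invisible(x)
}

#' Generate a normal (healthy) RR-interval sequence
#'
#' Intervals fluctuate around `normal_mean` with a slow AR(1) component
#' emulating autonomic heart-rate variability (fluctuations on the order of
#' tens of milliseconds). With `normal_sd = 0` the sequence is exactly
#' constant. Nonpositive draws are clipped to 1 ms with a warning.
#'
#' @param n Number of intervals (>= 1).
#' @param normal_mean Mean RR interval in ms (> 0), default 900.
#' @param normal_sd Marginal standard deviation in ms, default 40.
#' @param drift_coef AR(1) coefficient of the drift, default 0.9.
#' @param seed Integer seed.
#' @return An `rr_sequence` with no annotated segments.
#' @export
generate_rr_sequence <- function(n, normal_mean = 900, normal_sd = 40,
                                 drift_coef = 0.9, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (normal_mean <= 0) stop("normal_mean must be > 0")
  if (normal_sd < 0 || drift_coef < 0 || drift_coef >= 1) {
    stop("need normal_sd >= 0 and 0 <= drift_coef < 1")
  }
  set.seed(seed)
  if (normal_sd == 0) {
    x <- rep(normal_mean, n)
  } else {
    innov_sd <- normal_sd * sqrt(1 - drift_coef^2)
    a <- numeric(n)
    a[1] <- stats::rnorm(1, 0, normal_sd)  # stationary start
    if (n > 1) {
      e <- stats::rnorm(n - 1, 0, innov_sd)
      for (t in 2:n) a[t] <- drift_coef * a[t - 1] + e[t - 1]
    }
    x <- normal_mean + a
  }
  if (any(x <= 0)) {
    warning("nonpositive intervals clipped to 1 ms")
    x <- pmax(x, 1)
  }
  rr_sequence(x)
}

#' Insert abnormal low-RR segments into a sequence
#'
#' Replaces randomly placed non-overlapping stretches (separated by at least
#' one normal interval) with short intervals emulating ventricular
#' tachycardia / fibrillation, and annotates them. Segments start at indices
#' `>= min_start` so a full 1024-interval window always precedes them.
#'
#' @param seq An `rr_sequence`.
#' @param specs List (or data.frame with columns `mean_rr`, `length`) of
#'   segment specifications; `length` may be `NA` to draw uniformly from
#'   20--60 intervals.
#' @param min_start Smallest allowed start index (default 1024).
#' @param jitter_sd Within-segment jitter sd in ms (default 10).
#' @param seed Integer seed.
#' @return A new `rr_sequence` with annotated segments (in positional order).
#' @export
insert_abnormal_segments <- function(seq, specs, min_start = 1024,
                                     jitter_sd = 10, seed = 1) {
  stopifnot(inherits(seq, "rr_sequence"))
  if (is.data.frame(specs)) {
    specs <- lapply(seq_len(nrow(specs)), function(r) as.list(specs[r, ]))
  }
  if (length(specs) == 0) return(seq)
  set.seed(seed)
  n <- length(seq$intervals)
  K <- length(specs)
  means <- vapply(specs, function(s) as.numeric(s$mean_rr), numeric(1))
  if (any(means <= 0)) stop("each mean_rr must be > 0")
  lens <- vapply(specs, function(s) {
    L <- if (is.null(s$length) || is.na(s$length)) {
      sample(20:60, 1)
    } else {
      as.integer(s$length)
    }
    if (L < 2) stop("segment length must be >= 2 (j > i)")
    L
  }, integer(1))

  avail <- n - min_start + 1
  needed <- sum(lens) + (K - 1)  # >= 1 normal interval between segments
  slack <- avail - needed
  if (slack < 0) {
    stop(sprintf("placement error: %d intervals needed in [%d, %d], %d available",
                 needed, min_start, n, avail))
  }
  # Random packing: distribute the slack over the K + 1 gaps.
  extra <- as.vector(stats::rmultinom(1, slack, rep(1, K + 1)))
  x <- seq$intervals
  segments <- vector("list", K)
  pos <- min_start + extra[1]
  for (k in seq_len(K)) {
    i <- pos
    j <- i + lens[k] - 1
    x[i:j] <- pmax(stats::rnorm(lens[k], means[k], jitter_sd), 1)
    segments[[k]] <- list(i = i, j = j, mean_rr = means[k])
    pos <- j + 1 + 1 * (k < K) + extra[k + 1]  # mandatory gap then slack
  }
  rr_sequence(x, segments)
}

#' Label sliding windows of an RR sequence
#'
#' One row per window end index `e` in `[window, n]`; the window is labelled
#' abnormal iff interval `x_e` (the last interval of the window) lies inside
#' an annotated abnormal segment.
#'
#' @param seq An `rr_sequence` of length >= `window`.
#' @param window Window length in intervals (default 1024).
#' @return `data.frame` with columns `end_index`, `is_abnormal`.
#' @export
label_windows <- function(seq, window = 1024) {
  stopifnot(inherits(seq, "rr_sequence"))
  n <- length(seq$intervals)
  if (n < window) {
    stop(sprintf("insufficient data: need >= %d intervals, got %d", window, n))
  }
  e <- window:n
  abnormal <- rep(FALSE, length(e))
  for (seg in seq$segments) {
    abnormal[e >= seg$i & e <= seg$j] <- TRUE
  }
  data.frame(end_index = e, is_abnormal = abnormal)
}

#' Build a class-balanced training corpus of detector windows
#'
#' Generates `n_seq` independent RR sequences, inserts abnormal segments
#' with random mean RR and length into each, extracts windows with the given
#' stride (labelled by their last interval), and balances classes by
#' subsampling normal windows down to the abnormal count.
#'
#' @param n_seq Number of sequences (default 20).
#' @param seq_length Length of each sequence (default 1600).
#' @param n_segments Abnormal segments per sequence (default 6).
#' @param mean_rr_range Range the segment mean RRs are drawn from (ms).
#' @param normal_mean,normal_sd Normal-interval parameters (ms).
#' @param window Window length (default 1024).
#' @param stride Window stride (default 8).
#' @param seed Integer seed.
#' @return List with `windows` (matrix, one window per row) and `labels`
#'   (0 = normal, 1 = abnormal).
#' @export
make_detector_corpus <- function(n_seq = 20, seq_length = 1600,
                                 n_segments = 6,
                                 mean_rr_range = c(280, 560),
                                 normal_mean = 900, normal_sd = 40,
                                 window = 1024, stride = 8, seed = 1) {
  set.seed(seed)
  seeds <- sample.int(2^30, 2 * n_seq)
  win_list <- list()
  lab_list <- list()
  for (s in seq_len(n_seq)) {
    base <- generate_rr_sequence(seq_length, normal_mean, normal_sd,
                                 seed = seeds[2 * s - 1])
    specs <- lapply(seq_len(n_segments), function(k) {
      list(mean_rr = stats::runif(1, mean_rr_range[1], mean_rr_range[2]),
           length = NA)
    })
    seq_ab <- insert_abnormal_segments(base, specs, min_start = window,
                                       seed = seeds[2 * s])
    lab <- label_windows(seq_ab, window)
    keep <- lab$end_index[seq(1, nrow(lab), by = stride)]
    idx <- outer(keep - window + 1, 0:(window - 1), "+")
    win_list[[s]] <- matrix(seq_ab$intervals[idx], nrow = length(keep))
    lab_list[[s]] <- as.integer(lab$is_abnormal[match(keep, lab$end_index)])
  }
  windows <- do.call(rbind, win_list)
  labels <- unlist(lab_list)
  ab <- which(labels == 1)
  no <- which(labels == 0)
  if (length(ab) == 0) stop("corpus has no abnormal windows")
  no_keep <- sample(no, min(length(no), length(ab)))
  sel <- sample(c(ab, no_keep))
  list(windows = windows[sel, , drop = FALSE], labels = labels[sel])
}
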