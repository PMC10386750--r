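# RR-interval anomaly detector: a 1-D CNN (two conv -> batch-norm -> ReLU ->
# average-pool blocks, then a fully connected head with dropout) classifying
# 1024-interval windows as normal/abnormal, trained with cross-entropy and
# Adam. Sliding-window inference over a sequence and the latency value k of
# each annotated abnormal segment.

#' Binary cross-entropy loss
#'
#' `-(1/N) sum[y log(p) + (1 - y) log(1 - p)]` with probabilities clipped
#' away from 0 and 1 at 1e-12.
#'
#' @param probabilities Predicted positive-class probabilities in (0, 1).
#' @param labels Binary labels (0/1), same length.
#' @return Scalar loss (>= 0).
#' @export
cross_entropy_loss <- function(probabilities, labels) {
  if (length(probabilities) != length(labels)) {
    stop("shape error: probabilities and labels must have equal length")
  }
  if (length(labels) == 0) stop("shape error: empty input")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  p <- pmin(pmax(probabilities, 1e-12), 1 - 1e-12)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' One Adam update
#'
#' `m <- b1 m + (1-b1) g; v <- b2 v + (1-b2) g^2`, bias-corrected
#' `mhat = m/(1-b1^t)`, `vhat = v/(1-b2^t)`, then
#' `theta <- theta - alpha mhat / (sqrt(vhat) + eps)`.
#'
#' @param state List with `theta`, `m`, `v` (numerics or lists of numerics),
#'   step `t`, and hyperparameters `alpha`, `beta1`, `beta2`, `eps`.
#' @param gradients Gradients, shape-matched to `theta`.
#' @return Updated state with `t` incremented.
#' @export
#' @examples
#' s <- adam_state(0, alpha = 0.1, eps = 0)
#' adam_step(s, 1)$theta  # decreases by exactly alpha
adam_step <- function(state, gradients) {
  t <- state$t + 1L
  b1 <- state$beta1
  b2 <- state$beta2
  upd <- function(theta, m, v, g) {
    if (any(!is.finite(g))) stop("numerical error: non-finite gradient")
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    list(theta = theta - state$alpha * mhat / (sqrt(vhat) + state$eps),
         m = m, v = v)
  }
  if (is.list(state$theta)) {
    for (p in seq_along(state$theta)) {
      r <- upd(state$theta[[p]], state$m[[p]], state$v[[p]], gradients[[p]])
      state$theta[[p]] <- r$theta
      state$m[[p]] <- r$m
      state$v[[p]] <- r$v
    }
  } else {
    r <- upd(state$theta, state$m, state$v, gradients)
    state$theta <- r$theta
    state$m <- r$m
    state$v <- r$v
  }
  state$t <- t
  state
}

#' Initial Adam state
#'
#' @param theta Parameters (numeric or list of numerics).
#' @param alpha Learning rate, default 1e-3.
#' @param beta1,beta2 Moment decay rates, defaults 0.9 / 0.999.
#' @param eps Denominator guard, default 1e-8.
#' @return State list with zeroed moment estimates and `t = 0`.
#' @export
adam_state <- function(theta, alpha = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(theta = theta, m = zero(theta), v = zero(theta), t = 0L,
       alpha = alpha, beta1 = beta1, beta2 = beta2, eps = eps)
}

#' Configuration of the RR-interval anomaly detector
#'
#' @param window Window length in intervals, default 1024.
#' @param conv_channels Output channels of the two conv blocks, default
#'   `c(16, 32)`.
#' @param kernel_sizes Kernel widths, default `c(7, 5)`.
#' @param pool_sizes Average-pooling factors, default `c(4, 4)`.
#' @param fc_widths Widths of the two fully connected hidden layers, default
#'   `c(64, 32)`.
#' @param fc_dropout Dropout rate after the first FC hidden layer, default
#'   0.3.
#' @param alpha,beta1,beta2,eps Adam hyperparameters.
#' @param epochs Training epochs, default 25.
#' @param batch_size Minibatch size, default 32.
#' @param decision_threshold Abnormal-probability threshold in (0, 1),
#'   default 0.5.
#' @param seed Integer seed.
#' @return Object of class `detector_net_config`.
#' @export
detector_net_config <- function(window = 1024, conv_channels = c(16, 32),
                                kernel_sizes = c(7, 5), pool_sizes = c(4, 4),
                                fc_widths = c(64, 32), fc_dropout = 0.3,
                                alpha = 1e-3, beta1 = 0.9, beta2 = 0.999,
                                eps = 1e-8, epochs = 25, batch_size = 32,
                                decision_threshold = 0.5, seed = 42) {
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop("decision_threshold must lie strictly inside (0, 1)")
  }
  if (length(conv_channels) != 2 || length(kernel_sizes) != 2 ||
      length(pool_sizes) != 2) {
    stop("two conv blocks expected: channels, kernels, pools of length 2")
  }
  structure(list(window = window, conv_channels = conv_channels,
                 kernel_sizes = kernel_sizes, pool_sizes = pool_sizes,
                 fc_widths = fc_widths, fc_dropout = fc_dropout,
                 alpha = alpha, beta1 = beta1, beta2 = beta2, eps = eps,
                 epochs = epochs, batch_size = batch_size,
                 decision_threshold = decision_threshold, seed = seed),
            class = "detector_net_config")
}

# --- internal conv machinery ----------------------------------------------
# Activations travel as (B, L, C) arrays; inside a conv block they are
# flattened to (B*Lout) x C matrices whose columns are channels, so batch
# normalisation is plain column statistics.

im2col <- function(X, k) {
  d <- dim(X)  # (B, L, C)
  Lout <- d[2] - k + 1
  out <- matrix(0, d[1] * Lout, d[3] * k)
  for (t in seq_len(k)) {
    block <- X[, t:(t + Lout - 1), , drop = FALSE]
    dim(block) <- c(d[1] * Lout, d[3])
    out[, ((t - 1) * d[3] + 1):(t * d[3])] <- block
  }
  out
}

col2im <- function(dcol, B, L, C, k) {
  Lout <- L - k + 1
  dX <- array(0, c(B, L, C))
  for (t in seq_len(k)) {
    block <- dcol[, ((t - 1) * C + 1):(t * C), drop = FALSE]
    dim(block) <- c(B, Lout, C)
    dX[, t:(t + Lout - 1), ] <- dX[, t:(t + Lout - 1), , drop = FALSE] + block
  }
  dX
}

# Pooling is right-aligned: when L is not a multiple of p the *leading*
# positions are dropped, never the trailing ones. The classification label
# is defined by the last interval of the window, so the window end must
# survive every down-sampling stage.
avgpool_forward <- function(X, p) {
  d <- dim(X)  # (B, L, C)
  Lp <- d[2] %/% p
  off <- d[2] - p * Lp
  acc <- array(0, c(d[1], Lp, d[3]))
  for (q in seq_len(p)) {
    acc <- acc + X[, off + seq(q, p * Lp, by = p), , drop = FALSE]
  }
  acc / p
}

avgpool_backward <- function(dY, p, L) {
  d <- dim(dY)  # (B, Lp, C)
  off <- L - p * d[2]
  dX <- array(0, c(d[1], L, d[3]))
  for (q in seq_len(p)) {
    dX[, off + seq(q, p * d[2], by = p), ] <- dY / p
  }
  dX
}

BN_EPS <- 1e-5

detector_init <- function(config) {
  k <- config$kernel_sizes
  ch <- config$conv_channels
  Lp1 <- (config$window - k[1] + 1) %/% config$pool_sizes[1]
  Lp2 <- (Lp1 - k[2] + 1) %/% config$pool_sizes[2]
  if (Lp2 < 1) {
    stop("invalid config: window too short for the conv/pool geometry")
  }
  flat_dim <- Lp2 * ch[2]
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)),
                                   nin, nout)
  list(
    Wc1 = he(1 * k[1], ch[1]), bc1 = numeric(ch[1]),
    g1 = rep(1, ch[1]), be1 = numeric(ch[1]),
    Wc2 = he(ch[1] * k[2], ch[2]), bc2 = numeric(ch[2]),
    g2 = rep(1, ch[2]), be2 = numeric(ch[2]),
    Wf1 = he(flat_dim, config$fc_widths[1]), bf1 = numeric(config$fc_widths[1]),
    Wf2 = he(config$fc_widths[1], config$fc_widths[2]),
    bf2 = numeric(config$fc_widths[2]),
    Wo = he(config$fc_widths[2], 2), bo = numeric(2)
  )
}

detector_forward <- function(params, config, X, bn, training = FALSE) {
  B <- nrow(X)
  cache <- list()
  A <- array(X, c(B, ncol(X), 1))
  for (blk in 1:2) {
    k <- config$kernel_sizes[blk]
    p <- config$pool_sizes[blk]
    W <- params[[paste0("Wc", blk)]]
    Xcol <- im2col(A, k)
    Y <- sweep(Xcol %*% W, 2, params[[paste0("bc", blk)]], "+")
    if (training) {
      mu <- colMeans(Y)
      v <- colMeans(Y^2) - mu^2
      bn[[paste0("mean", blk)]] <- 0.9 * bn[[paste0("mean", blk)]] + 0.1 * mu
      bn[[paste0("var", blk)]] <- 0.9 * bn[[paste0("var", blk)]] + 0.1 * v
    } else {
      mu <- bn[[paste0("mean", blk)]]
      v <- bn[[paste0("var", blk)]]
    }
    Yhat <- sweep(sweep(Y, 2, mu), 2, sqrt(v + BN_EPS), "/")
    Z <- sweep(sweep(Yhat, 2, params[[paste0("g", blk)]], "*"), 2,
               params[[paste0("be", blk)]], "+")
    R <- pmax(Z, 0)
    Lout <- dim(A)[2] - k + 1
    Rarr <- R
    dim(Rarr) <- c(B, Lout, ncol(R))
    P <- avgpool_forward(Rarr, p)
    cache[[blk]] <- list(in_dim = dim(A), Xcol = Xcol, Y = Y, Yhat = Yhat,
                         Z = Z, mu = mu, v = v, Lout = Lout)
    A <- P
  }
  flat <- A
  dim(flat) <- c(B, prod(dim(A)[2:3]))
  cache$flat_in_dim <- dim(A)
  H1 <- sweep(flat %*% params$Wf1, 2, params$bf1, "+")
  A1 <- pmax(H1, 0)
  if (training && config$fc_dropout > 0) {
    mask <- matrix(stats::runif(length(A1)) >= config$fc_dropout, B) /
      (1 - config$fc_dropout)
    cache$drop_mask <- mask
    A1 <- A1 * mask
  }
  H2 <- sweep(A1 %*% params$Wf2, 2, params$bf2, "+")
  A2 <- pmax(H2, 0)
  logits <- sweep(A2 %*% params$Wo, 2, params$bo, "+")
  mx <- pmax(logits[, 1], logits[, 2])
  ex <- exp(logits - mx)
  prob <- ex / rowSums(ex)
  cache <- c(cache, list(flat = flat, H1 = H1, A1 = A1, H2 = H2, A2 = A2,
                         logits = logits, prob = prob, bn = bn))
  cache
}

detector_backward <- function(params, config, cache, labels) {
  B <- length(labels)
  grads <- list()
  dlogits <- cache$prob
  dlogits[cbind(seq_len(B), labels + 1)] <-
    dlogits[cbind(seq_len(B), labels + 1)] - 1
  dlogits <- dlogits / B
  grads$Wo <- t(cache$A2) %*% dlogits
  grads$bo <- colSums(dlogits)
  dA2 <- dlogits %*% t(params$Wo)
  dH2 <- dA2 * (cache$H2 > 0)
  grads$Wf2 <- t(cache$A1) %*% dH2
  grads$bf2 <- colSums(dH2)
  dA1 <- dH2 %*% t(params$Wf2)
  if (!is.null(cache$drop_mask)) dA1 <- dA1 * cache$drop_mask
  dH1 <- dA1 * (cache$H1 > 0)
  grads$Wf1 <- t(cache$flat) %*% dH1
  grads$bf1 <- colSums(dH1)
  dflat <- dH1 %*% t(params$Wf1)
  dA <- dflat
  dim(dA) <- cache$flat_in_dim
  for (blk in 2:1) {
    cc <- cache[[blk]]
    k <- config$kernel_sizes[blk]
    p <- config$pool_sizes[blk]
    dR <- avgpool_backward(dA, p, cc$Lout)
    dim(dR) <- c(dim(dR)[1] * cc$Lout, dim(dR)[3])
    dZ <- dR * (cc$Z > 0)
    grads[[paste0("g", blk)]] <- colSums(dZ * cc$Yhat)
    grads[[paste0("be", blk)]] <- colSums(dZ)
    # batch-norm backward, per channel (= per column)
    N <- nrow(dZ)
    dYhat <- sweep(dZ, 2, params[[paste0("g", blk)]], "*")
    inv_sd <- 1 / sqrt(cc$v + BN_EPS)
    Ymu <- sweep(cc$Y, 2, cc$mu)
    dvar <- colSums(dYhat * Ymu) * (-0.5) * inv_sd^3
    dmu <- colSums(dYhat) * (-inv_sd) + dvar * colMeans(-2 * Ymu)
    dY <- sweep(dYhat, 2, inv_sd, "*") +
      sweep(Ymu, 2, 2 * dvar / N, "*") +
      matrix(rep(dmu / N, each = N), N)
    grads[[paste0("Wc", blk)]] <- t(cc$Xcol) %*% dY
    grads[[paste0("bc", blk)]] <- colSums(dY)
    if (blk > 1) {
      dXcol <- dY %*% t(params[[paste0("Wc", blk)]])
      dA <- col2im(dXcol, cc$in_dim[1], cc$in_dim[2], cc$in_dim[3], k)
    }
  }
  grads[names(params)]
}

#' Train the RR-interval anomaly detector
#'
#' Windows are standardised with global training-set statistics (one mean
#' and one standard deviation over all training intervals, so the absolute
#' RR level — the physiologically meaningful signal — survives
#' standardisation), then fed to the CNN. Training
#' minimises cross-entropy with Adam; a stratified 15% validation split is
#' scored (inference mode) after every epoch.
#'
#' @param windows Numeric matrix, one window of `config$window` RR intervals
#'   (ms) per row.
#' @param labels Binary labels (0 normal, 1 abnormal); both classes must be
#'   present.
#' @param config A [detector_net_config()].
#' @param verbose Print progress every 5 epochs.
#' @return Object of class `rr_detector` with parameters, batch-norm running
#'   statistics, the global scaling constant and a training log (`epoch`,
#'   `loss`, `val_accuracy`).
#' @export
train_detector <- function(windows, labels, config = detector_net_config(),
                           verbose = FALSE) {
  stopifnot(inherits(config, "detector_net_config"))
  windows <- as.matrix(windows)
  labels <- as.integer(labels)
  if (ncol(windows) != config$window) {
    stop(sprintf("windows must have %d columns", config$window))
  }
  if (length(unique(labels)) < 2) {
    stop("class-balance error: both classes must be present")
  }
  set.seed(config$seed)
  global_mean <- mean(windows)
  global_sd <- stats::sd(as.numeric(windows))
  if (global_sd == 0) global_sd <- 1
  X <- (windows - global_mean) / global_sd

  n <- nrow(X)
  val_idx <- unlist(lapply(c(0, 1), function(cl) {
    ids <- which(labels == cl)
    sample(ids, max(1, round(0.15 * length(ids))))
  }))
  tr_idx <- setdiff(seq_len(n), val_idx)

  params <- detector_init(config)
  ch <- config$conv_channels
  bn <- list(mean1 = numeric(ch[1]), var1 = rep(1, ch[1]),
             mean2 = numeric(ch[2]), var2 = rep(1, ch[2]))
  state <- adam_state(params, config$alpha, config$beta1, config$beta2,
                      config$eps)
  ntr <- length(tr_idx)
  bs <- min(config$batch_size, ntr)
  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    starts <- seq(1, ntr, by = bs)
    losses <- c()
    for (s in starts) {
      idx <- ord[s:min(s + bs - 1, ntr)]
      if (length(idx) < 2) next  # batch norm needs at least 2 samples
      cache <- detector_forward(state$theta, config, X[idx, , drop = FALSE],
                                bn, training = TRUE)
      bn <- cache$bn
      loss <- cross_entropy_loss(cache$prob[, 2], labels[idx])
      if (!is.finite(loss)) stop("divergence error: non-finite loss")
      losses <- c(losses, loss)
      grads <- detector_backward(state$theta, config, cache, labels[idx])
      state <- adam_step(state, grads)
    }
    val_cache <- detector_forward(state$theta, config,
                                  X[val_idx, , drop = FALSE], bn,
                                  training = FALSE)
    val_pred <- as.integer(val_cache$prob[, 2] >= config$decision_threshold)
    val_acc <- mean(val_pred == labels[val_idx])
    log_rows[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                                    val_accuracy = val_acc)
    if (verbose && epoch %% 5 == 0) {
      message(sprintf("epoch %d: loss %.4f, val acc %.3f", epoch,
                      mean(losses), val_acc))
    }
  }
  structure(list(params = state$theta, bn = bn, global_mean = global_mean,
                 global_sd = global_sd, config = config,
                 log = do.call(rbind, log_rows)),
            class = "rr_detector")
}

#' Abnormality probability for RR windows
#'
#' @param model An `rr_detector`.
#' @param windows Matrix of windows (one per row) or a single vector.
#' @return Vector of abnormal-class probabilities.
#' @export
predict_detector <- function(model, windows) {
  stopifnot(inherits(model, "rr_detector"))
  if (is.null(dim(windows))) windows <- matrix(windows, nrow = 1)
  windows <- as.matrix(windows)
  if (ncol(windows) != model$config$window) {
    stop(sprintf("windows must have %d columns", model$config$window))
  }
  X <- (windows - model$global_mean) / model$global_sd
  out <- numeric(nrow(X))
  starts <- seq(1, nrow(X), by = 256)
  for (s in starts) {
    idx <- s:min(s + 255, nrow(X))
    cache <- detector_forward(model$params, model$config,
                              X[idx, , drop = FALSE], model$bn,
                              training = FALSE)
    out[idx] <- cache$prob[, 2]
  }
  out
}

#' Sliding-window detection over an RR sequence
#'
#' Evaluates every subsequence `x_m .. x_{m+window-1}`; the flag at end
#' index `e = m + window - 1` is set iff the abnormal-class probability is
#' at or above the threshold. Exactly `n - window + 1` flags are emitted.
#'
#' @param model An `rr_detector`.
#' @param seq An `rr_sequence` with `n >= window` intervals.
#' @param threshold Decision threshold; defaults to the model's configured
#'   one.
#' @return Object of class `detection_result`: list with `flags`
#'   (`data.frame` of `end_index`, `prob`, `flag`), the sequence `segments`,
#'   and `window`.
#' @export
sliding_window_detect <- function(model, seq, threshold = NULL) {
  stopifnot(inherits(model, "rr_detector"), inherits(seq, "rr_sequence"))
  window <- model$config$window
  n <- length(seq$intervals)
  if (n < window) {
    stop(sprintf(
      "insufficient data: the model must accumulate %d or more consecutive RR intervals (got %d)",
      window, n))
  }
  if (is.null(threshold)) threshold <- model$config$decision_threshold
  m <- n - window + 1
  idx <- outer(seq_len(m), 0:(window - 1), "+")
  X <- matrix(seq$intervals[idx], m, window)
  prob <- predict_detector(model, X)
  structure(list(
    flags = data.frame(end_index = window:n, prob = prob,
                       flag = prob >= threshold),
    segments = seq$segments,
    window = window
  ), class = "detection_result")
}

#' Latency value k of an abnormal segment
#'
#' The first flagged window whose end index `e` is at or after the segment
#' start `i` detects the segment; `k = max(e - i, 1)` (a flag at the window
#' ending exactly at `x_i` yields `k = 1`, keeping `k` a positive integer).
#' Flags strictly before `i` that fall outside every annotated segment are
#' counted as false alarms, not detections.
#'
#' @param result A `detection_result`.
#' @param segment List with `i`, `j` (`j > i >= window`).
#' @return List with `detected` (logical), `k` (positive integer or `NA`),
#'   and `false_alarms` (count before `i`).
#' @export
latency_k <- function(result, segment) {
  stopifnot(inherits(result, "detection_result"))
  i <- segment$i
  j <- segment$j
  if (is.null(i) || is.null(j) || j <= i || i < result$window) {
    stop(sprintf("segment must satisfy j > i >= %d", result$window))
  }
  flags <- result$flags
  if (max(flags$end_index) < j) {
    stop("range error: detection result does not cover the segment")
  }
  in_any_segment <- rep(FALSE, nrow(flags))
  for (seg in result$segments) {
    in_any_segment[flags$end_index >= seg$i & flags$end_index <= seg$j] <- TRUE
  }
  fa <- sum(flags$flag & flags$end_index < i & !in_any_segment)
  hits <- flags$end_index[flags$flag & flags$end_index >= i]
  if (length(hits) == 0) {
    return(list(detected = FALSE, k = NA_integer_, false_alarms = fa))
  }
  list(detected = TRUE, k = max(min(hits) - i, 1L), false_alarms = fa)
}

#' Latency experiment over all annotated segments
#'
#' Runs sliding-window detection and reports, per segment, its realized mean
#' RR, the latency value k and success (`k <= max_k`), plus an overall
#' summary.
#'
#' @param model An `rr_detector`.
#' @param seq An `rr_sequence` with at least one annotated segment.
#' @param max_k Success bound on k, default 10.
#' @param threshold Optional decision-threshold override.
#' @return Object of class `latency_experiment`: list with `table`
#'   (`data.frame`: segment, average_rr_ms, latency_k, result), `n_success`,
#'   `max_latency`, and the raw `detection`.
#' @export
evaluate_latency_experiment <- function(model, seq, max_k = 10,
                                        threshold = NULL) {
  stopifnot(inherits(seq, "rr_sequence"))
  if (length(seq$segments) == 0) {
    stop("sequence carries no annotated abnormal segments")
  }
  det <- sliding_window_detect(model, seq, threshold)
  rows <- lapply(seq_along(seq$segments), function(s) {
    seg <- seq$segments[[s]]
    lat <- latency_k(det, seg)
    data.frame(segment = s,
               average_rr_ms = mean(seq$intervals[seg$i:seg$j]),
               latency_k = if (lat$detected) lat$k else NA_integer_,
               result = if (lat$detected && lat$k <= max_k) "success"
                        else "failure")
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 n_success = sum(tab$result == "success"),
                 max_latency = if (all(is.na(tab$latency_k))) NA_integer_
                               else max(tab$latency_k, na.rm = TRUE),
                 max_k = max_k,
                 detection = det),
            class = "latency_experiment")
}

#' @export
print.latency_experiment <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("%d/%d segments detected with k <= %d (max k = %s)\n",
              x$n_success, nrow(x$table), x$max_k,
              ifelse(is.na(x$max_latency), "none", x$max_latency)))
  invisible(x)
}
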