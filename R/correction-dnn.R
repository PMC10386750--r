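# Heart-rate correction network: fully connected 9 -> 64 -> 128 -> 256 ->
# 128 -> 1, PReLU on the three hidden layers, dropout 0.2/0.3/0.4, mean
# squared error loss, Adagrad updates. Forward, backward and the optimizer
# are implemented directly on base matrices.

CORRECTION_FEATURES <- c("direction", "angle", "gender", "height", "weight",
                         "age", "distance", "motion_status", "radar_hr")

#' Mean squared error loss
#'
#' `(1/n) sum (y - yhat)^2`; symmetric and nonnegative.
#'
#' @param predicted,true Equal-length numeric vectors (BPM).
#' @return Scalar loss.
#' @export
mse_loss <- function(predicted, true) {
  if (length(predicted) != length(true)) {
    stop("shape error: predicted and true must have equal length")
  }
  if (length(true) == 0) stop("shape error: empty input")
  mean((true - predicted)^2)
}

#' One Adagrad update
#'
#' Per parameter: `G <- G + g^2; theta <- theta - eta * g / sqrt(G + eps)`.
#' Accumulated squared gradients are nonnegative and nondecreasing, so the
#' effective step size for a constant gradient shrinks over time.
#'
#' @param state List with `theta` and `G` (numeric vectors/arrays or lists
#'   of them, same shapes) and step counter `t`.
#' @param gradients Gradients, same shape as `theta`.
#' @param eta Global learning rate (> 0).
#' @param eps Small constant guarding the denominator.
#' @return Updated state.
#' @export
#' @examples
#' s <- adagrad_state(0)
#' s <- adagrad_step(s, 1, eta = 1, eps = 0)
#' s <- adagrad_step(s, 1, eta = 1, eps = 0)
#' s$theta  # -1 - 1/sqrt(2)
adagrad_step <- function(state, gradients, eta, eps = 1e-8) {
  stopifnot(eta > 0, eps >= 0)
  check_finite <- function(g, name) {
    if (any(!is.finite(g))) {
      stop(sprintf("numerical error: non-finite gradient in parameter %s",
                   name))
    }
  }
  if (is.list(state$theta)) {
    nm <- names(state$theta)
    for (p in seq_along(state$theta)) {
      g <- gradients[[p]]
      check_finite(g, if (is.null(nm)) p else nm[p])
      state$G[[p]] <- state$G[[p]] + g^2
      state$theta[[p]] <- state$theta[[p]] -
        eta * g / sqrt(state$G[[p]] + eps)
    }
  } else {
    check_finite(gradients, "theta")
    state$G <- state$G + gradients^2
    state$theta <- state$theta - eta * gradients / sqrt(state$G + eps)
  }
  state$t <- state$t + 1L
  state
}

#' Initial Adagrad state for a parameter set
#'
#' @param theta Parameters (numeric or list of numerics).
#' @return State list with zeroed accumulators.
#' @export
adagrad_state <- function(theta) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(theta = theta, G = zero(theta), t = 0L)
}

#' Configuration of the correction network
#'
#' @param layer_widths Widths of the four pre-output layers, default
#'   `c(64, 128, 256, 128)` (the 9-input layer has 64 neurons; the three
#'   hidden layers have 128, 256 and 128).
#' @param dropout_rates Dropout per layer aligned to `layer_widths`, default
#'   `c(0, 0.2, 0.3, 0.4)`.
#' @param eta Adagrad learning rate, default 0.01.
#' @param eps Adagrad epsilon, default 1e-8.
#' @param epochs Training epochs, default 200.
#' @param batch_size Minibatch size, default 64.
#' @param prelu_init Initial PReLU negative slope, default 0.25.
#' @param seed Integer seed for initialisation, shuffling and dropout.
#' @param input_dim Number of input features (9: eight condition factors
#'   plus the radar heart rate; the oximeter heart rate is the label, never
#'   a feature).
#' @return Object of class `correction_net_config`.
#' @export
correction_net_config <- function(layer_widths = c(64, 128, 256, 128),
                                  dropout_rates = c(0, 0.2, 0.3, 0.4),
                                  eta = 0.01, eps = 1e-8, epochs = 200,
                                  batch_size = 64, prelu_init = 0.25,
                                  seed = 42, input_dim = 9) {
  if (length(layer_widths) != length(dropout_rates)) {
    stop("layer_widths and dropout_rates must align")
  }
  if (any(dropout_rates < 0) || any(dropout_rates >= 1)) {
    stop("dropout rates must lie in [0, 1)")
  }
  if (eta <= 0 || eps <= 0) stop("eta and eps must be > 0")
  structure(list(layer_widths = layer_widths, dropout_rates = dropout_rates,
                 eta = eta, eps = eps, epochs = epochs,
                 batch_size = batch_size, prelu_init = prelu_init,
                 seed = seed, input_dim = input_dim),
            class = "correction_net_config")
}

# --- internal MLP machinery ------------------------------------------------

mlp_init <- function(config) {
  dims <- c(config$input_dim, config$layer_widths, 1)
  params <- list()
  for (l in seq_len(length(dims) - 1)) {
    fan_in <- dims[l]
    params[[paste0("W", l)]] <- matrix(
      stats::rnorm(fan_in * dims[l + 1], 0, sqrt(2 / fan_in)),
      fan_in, dims[l + 1])
    params[[paste0("b", l)]] <- numeric(dims[l + 1])
    # PReLU slopes on the three hidden layers (layers 2..4); the 64-neuron
    # input layer passes features through linearly.
    if (l >= 2 && l <= length(config$layer_widths)) {
      params[[paste0("a", l)]] <- config$prelu_init
    }
  }
  params
}

mlp_forward <- function(params, config, X, training = FALSE) {
  L <- length(config$layer_widths)
  cache <- list(A0 = X)
  A <- X
  for (l in seq_len(L)) {
    H <- sweep(A %*% params[[paste0("W", l)]], 2, params[[paste0("b", l)]],
               "+")
    cache[[paste0("H", l)]] <- H
    a_name <- paste0("a", l)
    if (!is.null(params[[a_name]])) {
      A <- ifelse(H > 0, H, params[[a_name]] * H)
    } else {
      A <- H
    }
    p <- config$dropout_rates[l]
    if (training && p > 0) {
      mask <- matrix(stats::runif(length(A)) >= p, nrow(A)) / (1 - p)
      cache[[paste0("M", l)]] <- mask
      A <- A * mask
    }
    cache[[paste0("A", l)]] <- A
  }
  out <- sweep(A %*% params[[paste0("W", L + 1)]], 2,
               params[[paste0("b", L + 1)]], "+")
  cache$out <- out
  cache
}

mlp_backward <- function(params, config, cache, dout) {
  L <- length(config$layer_widths)
  grads <- list()
  dA <- dout %*% t(params[[paste0("W", L + 1)]])
  grads[[paste0("W", L + 1)]] <- t(cache[[paste0("A", L)]]) %*% dout
  grads[[paste0("b", L + 1)]] <- colSums(dout)
  for (l in L:1) {
    mask <- cache[[paste0("M", l)]]
    if (!is.null(mask)) dA <- dA * mask
    H <- cache[[paste0("H", l)]]
    a_name <- paste0("a", l)
    if (!is.null(params[[a_name]])) {
      dH <- dA * ifelse(H > 0, 1, params[[a_name]])
      grads[[a_name]] <- sum(dA * ifelse(H > 0, 0, H))
    } else {
      dH <- dA
    }
    Aprev <- if (l == 1) cache$A0 else cache[[paste0("A", l - 1)]]
    grads[[paste0("W", l)]] <- t(Aprev) %*% dH
    grads[[paste0("b", l)]] <- colSums(dH)
    if (l > 1) dA <- dH %*% t(params[[paste0("W", l)]])
  }
  grads[names(params)]
}

standardize_columns <- function(X, centers = NULL, scales = NULL) {
  if (is.null(centers)) {
    centers <- colMeans(X)
    scales <- apply(X, 2, stats::sd)
    scales[scales == 0] <- 1
  }
  list(X = sweep(sweep(X, 2, centers), 2, scales, "/"),
       centers = centers, scales = scales)
}

correction_feature_matrix <- function(records) {
  missing <- setdiff(CORRECTION_FEATURES, names(records))
  if (length(missing) > 0) {
    stop(sprintf("validation error: missing feature column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  as.matrix(records[CORRECTION_FEATURES])
}

#' Train the heart-rate correction network
#'
#' Minimises the mean squared error between the network output and the
#' reference (oximeter) heart rate with Adagrad updates. Features are
#' z-scored with training-set statistics (ordinal factors enter as scaled
#' integer codes); the target is standardized for optimisation and mapped
#' back at inference. Dropout is active during training only.
#'
#' @param records `data.frame` of correction records carrying the nine
#'   feature columns plus `oximeter_hr` (the label).
#' @param config A [correction_net_config()].
#' @param verbose Print per-epoch loss every 20 epochs.
#' @return Object of class `hr_corrector` with the trained parameters,
#'   normalisation statistics and a training log (`epoch`, `loss`).
#' @export
train_corrector <- function(records, config = correction_net_config(),
                            verbose = FALSE) {
  stopifnot(inherits(config, "correction_net_config"))
  if (nrow(records) < 2) stop("need at least 2 records")
  if (!"oximeter_hr" %in% names(records)) {
    stop("validation error: missing feature column(s): oximeter_hr")
  }
  X_raw <- correction_feature_matrix(records)
  std <- standardize_columns(X_raw)
  y_raw <- records$oximeter_hr
  y_center <- mean(y_raw)
  y_scale <- stats::sd(y_raw)
  if (y_scale == 0) y_scale <- 1
  y <- (y_raw - y_center) / y_scale

  set.seed(config$seed)
  params <- mlp_init(config)
  state <- adagrad_state(params)
  n <- nrow(std$X)
  bs <- min(config$batch_size, n)
  log_loss <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = bs)
    batch_losses <- numeric(length(starts))
    for (k in seq_along(starts)) {
      idx <- ord[starts[k]:min(starts[k] + bs - 1, n)]
      Xb <- std$X[idx, , drop = FALSE]
      yb <- y[idx]
      cache <- mlp_forward(state$theta, config, Xb, training = TRUE)
      pred <- as.numeric(cache$out)
      loss <- mse_loss(pred, yb)
      if (!is.finite(loss)) {
        stop("divergence error: non-finite loss; lower the learning rate eta")
      }
      batch_losses[k] <- loss
      dout <- matrix(2 * (pred - yb) / length(yb), ncol = 1)
      grads <- mlp_backward(state$theta, config, cache, dout)
      state <- adagrad_step(state, grads, config$eta, config$eps)
    }
    log_loss[epoch] <- mean(batch_losses)
    if (verbose && epoch %% 20 == 0) {
      message(sprintf("epoch %d: loss %.5f", epoch, log_loss[epoch]))
    }
  }
  structure(list(params = state$theta, config = config,
                 centers = std$centers, scales = std$scales,
                 y_center = y_center, y_scale = y_scale,
                 log = data.frame(epoch = seq_len(config$epochs),
                                  loss = log_loss)),
            class = "hr_corrector")
}

#' Apply a trained corrector to records
#'
#' Deterministic inference (dropout disabled); outputs are clamped to the
#' physiological range 30--220 BPM.
#'
#' @param model An `hr_corrector`.
#' @param records `data.frame` carrying the nine feature columns.
#' @return Numeric vector of corrected heart rates (BPM).
#' @export
correct <- function(model, records) {
  stopifnot(inherits(model, "hr_corrector"))
  X_raw <- correction_feature_matrix(records)
  X <- standardize_columns(X_raw, model$centers, model$scales)$X
  cache <- mlp_forward(model$params, model$config, X, training = FALSE)
  pred <- as.numeric(cache$out) * model$y_scale + model$y_center
  pmin(pmax(pred, 30), 220)
}

#' Train/test evaluation of the correction pipeline
#'
#' Splits the records, trains the network on the training split and reports
#' held-out metrics of the measured (radar) and corrected values against the
#' reference, plus percent reductions.
#'
#' @param records Correction records incl. `radar_hr` and `oximeter_hr`.
#' @param config A [correction_net_config()].
#' @param test_fraction Held-out fraction, default 0.2.
#' @param seed Seed for the split.
#' @return List with `model`, `measured` and `corrected` metric reports,
#'   `reduction_pct`, and the held-out `test_index`.
#' @export
evaluate_correction <- function(records, config = correction_net_config(),
                                test_fraction = 0.2, seed = 99) {
  set.seed(seed)
  n <- nrow(records)
  test_idx <- sort(sample.int(n, round(test_fraction * n)))
  train <- records[-test_idx, , drop = FALSE]
  test <- records[test_idx, , drop = FALSE]
  model <- train_corrector(train, config)
  corrected <- correct(model, test)
  measured_rep <- error_metrics(test$oximeter_hr, test$radar_hr)
  corrected_rep <- error_metrics(test$oximeter_hr, corrected)
  list(model = model,
       measured = measured_rep,
       corrected = corrected_rep,
       reduction_pct = percent_reduction(measured_rep, corrected_rep),
       test_index = test_idx)
}
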