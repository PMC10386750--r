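# Error metrics (MAE, MSE, MRE), percent-reduction summaries, and Kendall
# tau-b with tie correction (C++ merge-sort backend).

#' Error metrics between reference and estimated heart rates
#'
#' MAE = mean |y - yhat|, MSE = mean (y - yhat)^2, MRE = mean |y - yhat| / y.
#'
#' @param true Reference values (BPM); must be nonzero for the MRE.
#' @param predicted Estimated values, same length.
#' @return Object of class `metrics_report`: list with `mae`, `mse`, `mre`,
#'   `n`.
#' @export
#' @examples
#' error_metrics(c(100, 100), c(90, 110))
error_metrics <- function(true, predicted) {
  if (length(true) != length(predicted)) {
    stop("shape error: true and predicted must have equal length")
  }
  if (length(true) == 0) stop("shape error: empty input")
  if (any(!is.finite(true)) || any(!is.finite(predicted))) {
    stop("inputs must be finite")
  }
  if (any(true == 0)) stop("MRE undefined: true values contain zero")
  d <- true - predicted
  structure(list(mae = mean(abs(d)), mse = mean(d^2),
                 mre = mean(abs(d) / abs(true)), n = length(true)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("MAE %.4f  MSE %.4f  MRE %.4f  (n = %d)\n",
              x$mae, x$mse, x$mre, x$n))
  invisible(x)
}

#' Percent reduction of error metrics
#'
#' `100 (before - after) / before` per metric; reported to full precision
#' (round to 2 decimals for display).
#'
#' @param before,after `metrics_report` objects, or named numeric vectors
#'   containing `mae`, `mse`, `mre`.
#' @return Named numeric vector of percent reductions.
#' @export
#' @examples
#' round(percent_reduction(c(mae = 21.48, mse = 484.92, mre = 0.245),
#'                         c(mae = 2.56, mse = 10.30, mre = 0.029)), 2)
percent_reduction <- function(before, after) {
  pick <- function(x) {
    if (inherits(x, "metrics_report")) x <- unlist(x[c("mae", "mse", "mre")])
    if (!all(c("mae", "mse", "mre") %in% names(x))) {
      stop("before/after must carry mae, mse and mre")
    }
    x[c("mae", "mse", "mre")]
  }
  b <- pick(before)
  a <- pick(after)
  if (any(b <= 0)) stop("undefined reduction: before metrics must be > 0")
  100 * (b - a) / b
}

#' Kendall tau-b rank correlation
#'
#' Tie-corrected Kendall correlation,
#' `tau_b = (C - D) / sqrt((n0 - n1) (n0 - n2))` with `C`/`D` the concordant
#' and discordant pair counts and `n1`, `n2` tie terms, computed in
#' O(n log n) by inversion counting in C++. Symmetric in its arguments;
#' negating one argument flips the sign.
#'
#' @param a,b Numeric vectors of equal length >= 2 (ordinal factors are
#'   passed as their integer codes).
#' @return Coefficient in `[-1, 1]`.
#' @export
kendall_tau_b <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) stop("inputs must be numeric")
  if (length(a) != length(b)) stop("shape error: unequal lengths")
  if (length(a) < 2) stop("need at least two observations")
  if (anyNA(a) || anyNA(b)) stop("inputs must not contain NA")
  out <- kendall_tau_b_cpp(as.numeric(a), as.numeric(b))
  if (is.na(out)) {
    stop("tau-b undefined: an argument is completely tied")
  }
  out
}
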