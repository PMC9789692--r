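#' Adjusted coefficient of determination
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)` with `R2` computed from residual
#' and total sums of squares about the mean of the observations.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param n_params Number of fitted parameters `p`.
#' @return Adjusted R-squared; `NA` (with a warning) when the observations
#'   have zero variance.
#' @export
adjusted_r2 <- function(observed, predicted, n_params) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (n <= n_params + 1)
    stop("need more observations than parameters + 1", call. = FALSE)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    warning("observations have zero variance: adjusted R2 undefined",
            call. = FALSE)
    return(NA_real_)
  }
  r2 <- 1 - sum((observed - predicted)^2) / sst
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

#' Bayesian information criterion (Gaussian form)
#'
#' `n * log(SSE/n) + (p + 1) * log(n)`, the profile-likelihood BIC for
#' homoscedastic Gaussian errors with the residual variance counted as a
#' parameter.  Only differences between BIC values computed on the same
#' data are meaningful.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param n_params Number of fitted mean parameters `p`.
#' @return BIC value; `-Inf` (with a warning) for a perfect fit.
#' @export
bic_gaussian <- function(observed, predicted, n_params) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (n < 1) stop("empty data", call. = FALSE)
  sse <- sum((observed - predicted)^2)
  if (sse == 0) {
    warning("zero residual sum of squares: BIC is -Inf", call. = FALSE)
    return(-Inf)
  }
  n * log(sse / n) + (n_params + 1) * log(n)
}

#' Residual-bias regression
#'
#' Regresses the residuals (observed - predicted) on the centered
#' predictions, `r_i = b0 + b1 * (y_i - mean(y)) + e_i`.  An unbiased
#' predictor gives intercept `b0` near zero (no scale difference), slope
#' `b1` near zero (no prediction bias), and a precision near one, where
#' precision is `1 - R2_adj` of this residual regression (residuals
#' uncorrelated with the predictions), clamped into `[0, 1]`.
#'
#' @param observed,predicted Numeric vectors (>= 3 pairs).
#' @return A list with `b0`, `b1` and `precision`.  With constant
#'   predictions the slope is `NA` (flagged by a warning); with all-zero
#'   residuals `b0 = b1 = 0` and `precision` is `NA`.
#' @export
residual_bias <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  r <- observed - predicted
  x <- predicted - mean(predicted)
  if (all(r == 0))
    return(list(b0 = 0, b1 = 0, precision = NA_real_))
  if (all(x == 0)) {
    warning("constant predictions: bias slope undefined", call. = FALSE)
    return(list(b0 = mean(r), b1 = NA_real_, precision = NA_real_))
  }
  fit <- stats::lm(r ~ x)
  co <- stats::coef(fit)
  r2a <- adjusted_r2(r, stats::fitted(fit), 1L)
  precision <- if (is.na(r2a)) NA_real_ else min(1, max(0, 1 - r2a))
  list(b0 = unname(co[1]), b1 = unname(co[2]), precision = precision)
}
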