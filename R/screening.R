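#' Orthogonal polynomial contrasts over unequally spaced dose levels
#'
#' One-way ANOVA of a response over dietary levels plus single-degree
#' linear and quadratic contrasts built by orthogonalizing `(level,
#' level^2)` against the intercept on the actual (unequal) spacing and
#' replication.  Contrast F tests use the within-treatment mean square
#' from the full one-way decomposition.
#'
#' @param level Numeric dietary level per observation (>= 3 distinct
#'   values, >= 2 observations per level).
#' @param value Numeric response per observation.
#' @param variable Optional response name carried into the result.
#' @return A list of class `contrast_result` with `variable`, `p_anova`,
#'   `p_linear`, `p_quadratic`, `f_values` (named vector), `estimates`
#'   (linear and quadratic contrast estimates) and `n_used`.
#' @export
polynomial_contrasts <- function(level, value, variable = "response") {
  stopifnot(length(level) == length(value))
  ok <- is.finite(level) & is.finite(value)
  level <- level[ok]; value <- value[ok]
  lv <- sort(unique(level))
  if (length(lv) < 3)
    stop("need at least 3 distinct dose levels", call. = FALSE)
  if (any(table(level) < 2))
    stop("need at least 2 observations per level", call. = FALSE)
  n <- length(value)
  k <- length(lv)
  fac <- factor(level)
  anova_fit <- stats::aov(value ~ fac)
  an <- summary(anova_fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  df_e <- an["Residuals", "Df"]
  p_anova <- an["fac", "Pr(>F)"]
  f_anova <- an["fac", "F value"]

  # observation-level orthogonal polynomial contrast vectors
  P <- stats::poly(level, degree = 2)
  contrast_test <- function(cvec) {
    est <- sum(cvec * value)
    ss <- est^2 / sum(cvec^2)
    f <- ss / mse
    list(estimate = est, f = f,
         p = stats::pf(f, 1, df_e, lower.tail = FALSE))
  }
  lin <- contrast_test(P[, 1])
  quad <- contrast_test(P[, 2])
  structure(list(variable = variable,
                 p_anova = p_anova,
                 p_linear = lin$p,
                 p_quadratic = quad$p,
                 f_values = c(anova = f_anova, linear = lin$f,
                              quadratic = quad$f),
                 estimates = c(linear = lin$estimate,
                               quadratic = quad$estimate),
                 n_used = n),
            class = "contrast_result")
}

#' Within-treatment outlier screen
#'
#' Flags observations further than `k` within-treatment standard
#' deviations from their treatment mean, with the mean and SD computed
#' leaving the candidate observation out: with as few as seven birds per
#' treatment an extreme value inflates the in-sample SD enough to mask
#' itself (the in-sample z-score cannot exceed `(n-1)/sqrt(n)`), so the
#' leave-one-out form is required for the screen to have any power.  At
#' most one observation (the most extreme flagged one) is removed per
#' treatment per pass.
#'
#' @param value Numeric response per observation.
#' @param treatment Treatment identifier per observation.
#' @param k Standard-deviation multiplier (> 0, default 3).
#' @return A list with `keep` (logical vector, `TRUE` for retained
#'   observations) and `report` (data frame of flagged observations with
#'   their z-scores).
#' @export
outlier_screen <- function(value, treatment, k = 3) {
  stopifnot(length(value) == length(treatment), k > 0)
  keep <- rep(TRUE, length(value))
  rows <- integer(0); zs <- numeric(0); trt <- character(0)
  for (t in unique(treatment)) {
    idx <- which(treatment == t)
    if (length(idx) < 3) next
    z <- vapply(seq_along(idx), function(i) {
      rest <- value[idx][-i]
      s <- stats::sd(rest)
      if (!is.finite(s) || s == 0) return(Inf * abs(value[idx][i] -
                                                      mean(rest)))
      abs(value[idx][i] - mean(rest)) / s
    }, numeric(1))
    z[is.nan(z)] <- 0  # identical values throughout
    flagged <- which(z > k)
    if (length(flagged)) {
      worst <- flagged[which.max(z[flagged])]
      keep[idx[worst]] <- FALSE
      rows <- c(rows, idx[worst])
      zs <- c(zs, z[worst])
      trt <- c(trt, as.character(t))
    }
  }
  list(keep = keep,
       report = data.frame(row = rows, treatment = trt, z = zs))
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("%s: ANOVA p = %.3g, linear p = %.3g, quadratic p = %.3g (n = %d)\n",
              x$variable, x$p_anova, x$p_linear, x$p_quadratic, x$n_used))
  invisible(x)
}
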