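#' Saturation-kinetics response parameters
#'
#' Hill-type four-parameter response
#' `Y = (Rmin * km^n + Rmax * X^n) / (km^n + X^n)`, rising from `Rmin` at
#' zero intake towards the asymptote `Rmax`; `km` is the intake giving half
#' of `Rmax + Rmin` and `n` the apparent kinetic order.
#'
#' @param Rmax Asymptotic response, mg/kg^0.67/d.
#' @param Rmin Response at zero intake, mg/kg^0.67/d (`Rmax > Rmin >= 0`).
#' @param km Intake at half-range response, mg/kg^0.67/d (> 0).
#' @param n Apparent kinetic order (> 0, dimensionless).
#' @return An object of class `saturation_params`.
#' @export
saturation_params <- function(Rmax, Rmin, km, n) {
  stopifnot(Rmax > Rmin, Rmin >= 0, km > 0, n > 0)
  structure(list(Rmax = Rmax, Rmin = Rmin, km = km, n = n),
            class = "saturation_params")
}

#' Four-parameter monomolecular response parameters
#'
#' Diminishing-returns exponential response anchored at a maintenance
#' intake `Xm`.  The default `"shifted"` form is
#' `Y = Rmax - (Rmax + Rmin) * exp(-k * (X - Xm))`, an increasing curve
#' with asymptote `Rmax` that passes through `-Rmin` at `X = Xm`, so
#' `Rmin` is the magnitude of the minimum (negative) response and `Xm` the
#' intake at which the net response would be `-Rmin`.  The `"printed"`
#' form `Y = Rmax - Rmin * (1 - exp(-k * (X - Xm)))` is the verbatim
#' published equation; as written it is non-increasing in `X` and is kept
#' only for reference (see the methods vignette).
#'
#' @param Rmax Asymptotic response, mg/kg^0.67/d (> 0).
#' @param Rmin Minimum-response magnitude, mg/kg^0.67/d (>= 0).
#' @param k Rate constant per unit intake (> 0).
#' @param Xm Maintenance intake, mg/kg^0.67/d (>= 0).
#' @param form `"shifted"` (default) or `"printed"`.
#' @return An object of class `monomolecular_params`.
#' @export
monomolecular_params <- function(Rmax, Rmin, k, Xm, form = "shifted") {
  stopifnot(Rmax > 0, Rmin >= 0, k > 0, Xm >= 0)
  form <- match.arg(form, c("shifted", "printed"))
  structure(list(Rmax = Rmax, Rmin = Rmin, k = k, Xm = Xm, form = form),
            class = "monomolecular_params")
}

#' Evaluate the saturation-kinetics response
#'
#' @param p A [saturation_params()] object.
#' @param X Intake, mg/kg^0.67/d (>= 0); vectorized.
#' @return Predicted response at `X`.
#' @examples
#' p <- saturation_params(232, 21, 291, 3.413)
#' eval_saturation(p, 291)  # (232 + 21) / 2
#' @export
eval_saturation <- function(p, X) {
  stopifnot(inherits(p, "saturation_params"), all(X >= 0))
  # compute on the ratio (X/km)^n to avoid overflow of km^n at large n
  r <- (X / p$km)^p$n
  (p$Rmin + p$Rmax * r) / (1 + r)
}

#' Evaluate the four-parameter monomolecular response
#'
#' @param p A [monomolecular_params()] object.
#' @param X Intake, mg/kg^0.67/d (>= 0); vectorized.
#' @return Predicted response at `X`.
#' @export
eval_monomolecular <- function(p, X) {
  stopifnot(inherits(p, "monomolecular_params"), all(X >= 0))
  e <- exp(-p$k * (X - p$Xm))
  switch(p$form,
         shifted = p$Rmax - (p$Rmax + p$Rmin) * e,
         printed = p$Rmax - p$Rmin * (1 - e),
         stop("unknown monomolecular form: ", p$form, call. = FALSE))
}

#' Marginal efficiency curve dY/dX
#'
#' Closed-form derivative of the fitted response with respect to intake:
#' the instantaneous efficiency of converting additional arginine intake
#' into egg deposition.  For the saturation model,
#' `dY/dX = n * km^n * X^(n-1) * (Rmax - Rmin) / (km^n + X^n)^2`; for the
#' shifted monomolecular, `dY/dX = k * (Rmax + Rmin) * exp(-k (X - Xm))`.
#'
#' @param p A [saturation_params()] or [monomolecular_params()] object.
#' @param X Intake (>= 0); vectorized.
#' @return The derivative dY/dX at `X`.
#' @export
efficiency_curve <- function(p, X) {
  stopifnot(all(X >= 0))
  if (inherits(p, "saturation_params")) {
    r <- (X / p$km)^p$n
    # n (Rmax - Rmin) r / (X (1 + r)^2), written to stay finite at X = 0
    out <- ifelse(X == 0 & p$n > 1, 0,
                  p$n * (p$Rmax - p$Rmin) * r / (X * (1 + r)^2))
    if (p$n == 1) out[X == 0] <- (p$Rmax - p$Rmin) / p$km
    return(out)
  }
  if (inherits(p, "monomolecular_params")) {
    e <- exp(-p$k * (X - p$Xm))
    return(switch(p$form,
                  shifted = p$k * (p$Rmax + p$Rmin) * e,
                  printed = -p$k * p$Rmin * e))
  }
  stop("unsupported parameter object", call. = FALSE)
}

#' Maintenance intake from a fitted response
#'
#' The intake at which the net response crosses zero, read from the fitted
#' parameters: for the monomolecular family this is the anchor `Xm`
#' directly; for the saturation family it is `km * (Rmin/Rmax)^(1/n)`.
#' Both are per-kg-metabolic-weight values; multiplying by `BW^0.67`
#' (body weight in kg) gives the per-bird daily maintenance requirement.
#'
#' @param p A fitted parameter object or a [fit_response()] result.
#' @param body_weight Body weight in kg (default 1, i.e. return only the
#'   per-metabolic-kg value scaled by 1).
#' @return A list with `per_kg` (mg/kg^0.67/d) and `per_bird`
#'   (mg/bird/d at the supplied body weight).
#' @examples
#' maintenance_intake(saturation_params(232, 21, 291, 3.413))$per_kg  # 144
#' @export
maintenance_intake <- function(p, body_weight = 1) {
  if (inherits(p, "response_fit")) p <- p$params
  stopifnot(all(body_weight > 0))
  per_kg <- if (inherits(p, "monomolecular_params")) {
    p$Xm
  } else if (inherits(p, "saturation_params")) {
    if (p$Rmin == 0) {
      warning("Rmin = 0: maintenance intake is 0 under saturation kinetics",
              call. = FALSE)
      0
    } else {
      p$km * (p$Rmin / p$Rmax)^(1 / p$n)
    }
  } else stop("unsupported parameter object", call. = FALSE)
  list(per_kg = per_kg, per_bird = body_weight^0.67 * per_kg)
}

#' Intake at the maximum slope of the saturation response
#'
#' The inflection point of the Hill-type curve, where the marginal
#' efficiency dY/dX is largest: `km * ((n - 1)/(n + 1))^(1/n)`.  Exists
#' only for kinetic order `n > 1`.
#'
#' @param p A [saturation_params()] object with `n > 1`.
#' @return Intake at maximum slope, mg/kg^0.67/d.
#' @export
intake_at_max_slope <- function(p) {
  stopifnot(inherits(p, "saturation_params"))
  if (p$n <= 1)
    stop("no inflection point: kinetic order n must exceed 1",
         call. = FALSE)
  p$km * ((p$n - 1) / (p$n + 1))^(1 / p$n)
}

#' Intake at the maximum above-minimum average efficiency
#'
#' The intake maximizing `(Y(X) - Rmin) / X`, the average efficiency of
#' converting intake into response gained above the zero-intake baseline:
#' `km * (n - 1)^(1/n)` for the saturation model, defined for `n > 1`.
#'
#' @param p A [saturation_params()] object with `n > 1`.
#' @return Intake at maximum average efficiency, mg/kg^0.67/d.
#' @export
intake_at_max_efficiency <- function(p) {
  stopifnot(inherits(p, "saturation_params"))
  if (p$n <= 1)
    stop("average efficiency has no interior maximum for n <= 1",
         call. = FALSE)
  p$km * (p$n - 1)^(1 / p$n)
}

sat_fun <- function(X, Rmax, Rmin, km, n) {
  r <- (X / km)^n
  (Rmin + Rmax * r) / (1 + r)
}

mono_fun_shifted <- function(X, Rmax, Rmin, k, Xm)
  Rmax - (Rmax + Rmin) * exp(-k * (X - Xm))

#' Fit a response family by nonlinear least squares
#'
#' Fits the saturation-kinetics or (shifted) four-parameter monomolecular
#' response to standardized observations by Levenberg-Marquardt least
#' squares with multiple restarts.  An optional two-stage random-maximum
#' mode treats per-bird offsets in `Rmax` as random: offsets are estimated
#' from per-bird mean residuals, shrunk by the estimated variance ratio,
#' subtracted, and the curve refit.
#'
#' The shifted monomolecular curve
#' `Y = Rmax - (Rmax + Rmin) * exp(-k * (X - Xm))` determines only three
#' quantities from data: `Rmax`, `k`, and the composite
#' `B = (Rmax + Rmin) * exp(k * Xm)`; any `(Rmin, Xm)` pair with the same
#' composite gives the identical curve.  The fit therefore estimates the
#' identifiable reduced form `Y = Rmax - B * exp(-k * X)` and splits `B`
#' into `(Rmin, Xm)` at a fixed `Rmin` supplied through `Rmin_fixed`
#' (default 0, which makes `Xm` the intake at which the fitted net
#' response crosses zero).  The fitted curve itself does not depend on
#' this choice.
#'
#' @param data Data frame with columns `X` and `Y` (standardized intake and
#'   deposition, mg/kg^0.67/d) and, for the random-maximum mode, `bird_id`.
#' @param family `"saturation"` or `"monomolecular"`.
#' @param random_rmax Logical; use the two-stage random-maximum mode
#'   (default `FALSE`, plain fixed-effects nonlinear least squares).
#' @param start Optional named list of starting values overriding the
#'   data-driven defaults.
#' @param Rmin_fixed For the monomolecular family only: the value of
#'   `Rmin` at which the non-identified `(Rmin, Xm)` ridge is anchored.
#' @return An object of class `response_fit`: the fitted parameter object
#'   (`params`), standard errors (`se`), `r2_adj`, `bic`, `n_obs`,
#'   `fitted`, `residuals`, and for the random mode the shrunk per-bird
#'   offsets (`bird_effects`).
#' @export
fit_response <- function(data, family = c("saturation", "monomolecular"),
                         random_rmax = FALSE, start = NULL,
                         Rmin_fixed = 0) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data), all(c("X", "Y") %in% names(data)))
  X <- data$X; Y <- data$Y
  n_par <- 4L
  if (length(X) <= n_par)
    stop("need more observations than parameters", call. = FALSE)
  if (length(X) < 2L * n_par)
    warning("fewer than ", 2L * n_par,
            " observations: parameter estimates may be fragile",
            call. = FALSE)
  if (diff(range(X)) <= 0)
    stop("no spread in X: cannot fit a response curve", call. = FALSE)

  fit <- nls_response(X, Y, family, start)
  bird_effects <- NULL
  if (random_rmax) {
    if (!"bird_id" %in% names(data))
      stop("random_rmax = TRUE requires a bird_id column", call. = FALSE)
    # a bird-level shift in Rmax loads on each observation through
    # f = dY/dRmax (the saturated fraction of the curve at that intake);
    # with one record per bird the variance components are estimated by
    # regressing squared residuals on f^2, then per-bird shifts are
    # shrunk BLUP-style before refitting
    res <- Y - predict_family(fit$par, family, X)
    f <- rmax_loading(fit$par, family, X)
    mom <- stats::coef(stats::lm(I(res^2) ~ I(f^2)))
    sigma2_e <- max(mom[1], 1e-8)
    sigma2_b <- max(mom[2], 0)
    b_obs <- sigma2_b * f * res / (sigma2_b * f^2 + sigma2_e)
    by_bird <- tapply(b_obs, data$bird_id, mean)
    bird_effects <- as.numeric(by_bird)
    names(bird_effects) <- names(by_bird)
    fl <- f * bird_effects[as.character(data$bird_id)]
    Yc <- Y - fl
    fit <- nls_response(X, Yc, family, start = as.list(fit$par))
    Y <- Yc
  }

  pred <- predict_family(fit$par, family, X)
  if (family == "saturation") {
    params <- saturation_params(fit$par[["Rmax"]], fit$par[["Rmin"]],
                                fit$par[["km"]], fit$par[["n"]])
    se <- fit$se
  } else {
    split <- split_mono_ridge(fit, Rmin_fixed)
    params <- split$params
    se <- split$se
  }
  structure(list(family = family,
                 params = params,
                 se = se,
                 r2_adj = adjusted_r2(Y, pred, n_par),
                 bic = bic_gaussian(Y, pred, n_par),
                 n_obs = length(Y),
                 fitted = pred,
                 residuals = Y - pred,
                 bird_effects = bird_effects,
                 convergence = fit$convergence),
            class = "response_fit")
}

rmax_loading <- function(par, family, X) {
  if (family == "saturation") {
    r <- (X / par[["km"]])^par[["n"]]
    r / (1 + r)
  } else rep(1, length(X))
}

predict_family <- function(par, family, X) {
  if (family == "saturation")
    sat_fun(X, par[["Rmax"]], par[["Rmin"]], par[["km"]], par[["n"]])
  else
    par[["Rmax"]] - par[["B"]] * exp(-par[["k"]] * X)
}

# split the identifiable composite B = (Rmax + Rmin) exp(k Xm) into
# (Rmin, Xm) at a fixed Rmin; delta-method SE for Xm from the reduced fit
split_mono_ridge <- function(fit, Rmin_fixed) {
  stopifnot(Rmin_fixed >= 0)
  Rmax <- fit$par[["Rmax"]]; B <- fit$par[["B"]]; k <- fit$par[["k"]]
  Xm <- log(B / (Rmax + Rmin_fixed)) / k
  if (Xm < 0) {
    warning("implied maintenance anchor Xm is negative at Rmin = ",
            Rmin_fixed, "; clamped to 0", call. = FALSE)
    Xm <- 0
  }
  se_Xm <- NA_real_
  if (!is.null(fit$vcov) && all(is.finite(fit$vcov))) {
    g <- c(-1 / (k * (Rmax + Rmin_fixed)), 1 / (k * B), -Xm / k)
    v <- drop(t(g) %*% fit$vcov[c("Rmax", "B", "k"), c("Rmax", "B", "k")]
              %*% g)
    if (is.finite(v) && v >= 0) se_Xm <- sqrt(v)
  }
  list(params = monomolecular_params(Rmax, Rmin_fixed, k, Xm),
       se = c(Rmax = unname(fit$se[["Rmax"]]), Rmin = 0,
              k = unname(fit$se[["k"]]), Xm = se_Xm))
}

default_starts <- function(X, Y, family) {
  rmax0 <- max(Y)
  if (family == "saturation") {
    half <- (rmax0 + max(min(Y), 0)) / 2
    km0 <- tryCatch(stats::approx(Y, X, xout = half, ties = mean)$y,
                    error = function(e) NA_real_)
    if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(X)
    list(Rmax = rmax0, Rmin = max(min(Y), 1e-2), km = km0, n = 2)
  } else {
    k0 <- 2 / diff(range(X))
    list(Rmax = rmax0, B = max(rmax0 - min(Y), 1e-3) * exp(k0 * min(X)),
         k = k0)
  }
}

perturb_start <- function(s, f) lapply(s, function(v) v * f)

nls_response <- function(X, Y, family, start = NULL) {
  s0 <- if (is.null(start)) default_starts(X, Y, family) else start
  lower <- if (family == "saturation")
    c(Rmax = 1e-8, Rmin = 0, km = 1e-8, n = 1e-3)
  else
    c(Rmax = 1e-8, B = 1e-8, k = 1e-8)
  formula <- if (family == "saturation")
    Y ~ sat_fun(X, Rmax, Rmin, km, n)
  else
    Y ~ Rmax - B * exp(-k * X)
  df <- data.frame(X = X, Y = Y)
  starts <- list(s0, perturb_start(s0, 0.5), perturb_start(s0, 1.8))
  best <- NULL
  for (s in starts) {
    s <- as.list(pmax(unlist(s), lower + 1e-9))
    f <- tryCatch(
      minpack.lm::nlsLM(formula, data = df, start = s, lower = lower,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(f)) next
    dev <- sum(stats::residuals(f)^2)
    if (is.null(best) || dev < best$dev)
      best <- list(fit = f, dev = dev)
  }
  if (is.null(best))
    stop("response fit failed to converge from all starting points",
         call. = FALSE)
  par <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) {
                   out <- rep(NA_real_, length(par))
                   names(out) <- names(par)
                   out
                 })
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  list(par = par, se = se, vcov = vc, convergence = TRUE)
}

#' Broken-line (linear-plateau) regression
#'
#' Fits `Y = plateau - slope * max(0, breakpoint - X)`: a line rising with
#' slope `slope` up to the breakpoint, constant at `plateau` beyond it.
#' The breakpoint is profiled over a grid of 50 candidates between the 5th
#' and 95th percentiles of `X` (ordinary least squares for the other two
#' parameters at each candidate), then polished by local optimization in
#' the bracketing interval; ties break toward the smaller breakpoint.
#'
#' @param X Numeric predictor (e.g. intake).
#' @param Y Numeric response.
#' @param grid_n Number of breakpoint candidates (default 50).
#' @return An object of class `broken_line_fit` with elements `plateau`,
#'   `slope`, `breakpoint`, `se` (named vector; breakpoint SE from the
#'   profile curvature), `r2_adj`, `bic`, `n_obs`, `fitted`, `residuals`,
#'   and `identified` (`FALSE` when the breakpoint sits on the grid
#'   boundary or the slope vanishes).
#' @export
fit_broken_line <- function(X, Y, grid_n = 50L) {
  stopifnot(length(X) == length(Y))
  if (length(X) < 4L)
    stop("need at least 4 observations", call. = FALSE)
  lo <- stats::quantile(X, 0.05, names = FALSE)
  hi <- stats::quantile(X, 0.95, names = FALSE)
  grid <- seq(lo, hi, length.out = grid_n)
  # degenerate when no candidate splits the data
  if (all(X >= hi) || all(X <= lo) || lo == hi)
    stop("degenerate design: all X on one side of every candidate breakpoint",
         call. = FALSE)
  sse_at <- function(b) {
    z <- pmax(0, b - X)
    f <- stats::lm.fit(cbind(1, z), Y)
    sum(f$residuals^2)
  }
  sse <- vapply(grid, sse_at, numeric(1))
  i <- which(sse <= min(sse) + 1e-12)[1]  # tie-break: smaller breakpoint
  lo_i <- grid[max(1L, i - 1L)]
  hi_i <- grid[min(grid_n, i + 1L)]
  b <- if (lo_i < hi_i)
    stats::optimize(sse_at, c(lo_i, hi_i), tol = 1e-10)$minimum
  else grid[i]
  if (sse_at(grid[i]) < sse_at(b)) b <- grid[i]

  z <- pmax(0, b - X)
  fit <- stats::lm(Y ~ z)
  plateau <- unname(stats::coef(fit)[1])
  slope <- -unname(stats::coef(fit)[2])
  if (is.na(slope)) slope <- 0
  pred <- plateau - slope * pmax(0, b - X)
  res <- Y - pred
  n <- length(Y)
  sigma2 <- sum(res^2) / max(1, n - 3)
  # profile-curvature breakpoint SE: Var(b) ~ 2 sigma^2 / SSE''(b)
  h <- max(1e-4 * diff(range(X)), 1e-8)
  d2 <- (sse_at(b + h) - 2 * sse_at(b) + sse_at(b - h)) / h^2
  se_b <- if (is.finite(d2) && d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  se_lin <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) c(NA_real_, NA_real_))
  identified <- slope > sqrt(.Machine$double.eps) &&
    b > grid[1] + 1e-8 && b < grid[grid_n] - 1e-8
  structure(list(plateau = plateau, slope = slope, breakpoint = b,
                 se = c(plateau = unname(se_lin[1]),
                        slope = unname(se_lin[2]), breakpoint = se_b),
                 r2_adj = adjusted_r2(Y, pred, 3L),
                 bic = bic_gaussian(Y, pred, 3L),
                 n_obs = n, fitted = pred, residuals = res,
                 identified = identified),
            class = "broken_line_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  cat("Response fit (", x$family, "), n =", x$n_obs, "\n")
  p <- unclass(x$params)
  p$form <- NULL
  est <- unlist(p)
  print(round(rbind(estimate = est, se = x$se[seq_along(est)]), 4))
  cat(sprintf("R2_adj = %.4f, BIC = %.1f\n", x$r2_adj, x$bic))
  invisible(x)
}

#' @export
print.broken_line_fit <- function(x, ...) {
  cat("Broken-line fit: Y =", round(x$plateau, 2), "-",
      round(x$slope, 3), "* max(0,", round(x$breakpoint, 1), "- X)\n")
  cat(sprintf("R2_adj = %.4f, n = %d%s\n", x$r2_adj, x$n_obs,
              if (!x$identified) " (breakpoint not identified)" else ""))
  invisible(x)
}
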