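#' Corrected arginine intake axes
#'
#' Utilization efficiency is read from broken-line fits of deposition
#' against intake after crediting the arginine already committed to
#' maintenance and, optionally, supplied by body mobilization.  Three
#' supply axes are defined: `"total"` leaves intake untouched;
#' `"minus_maintenance"` subtracts the maintenance requirement;
#' `"minus_maintenance_plus_mobilization"` additionally counts mobilized
#' body arginine (negative mobilization, i.e. body loss) as supply, adding
#' `max(0, -mobilization)`.  Body gain is never subtracted.
#'
#' @param X Intake, mg/kg^0.67/d (>= 0); vectorized.
#' @param maintenance Maintenance intake on the same scale.
#' @param mobilization Arginine mobilization on the same scale (negative =
#'   body loss); ignored except in the third mode.
#' @param mode One of `"total"`, `"minus_maintenance"`,
#'   `"minus_maintenance_plus_mobilization"`.
#' @return Corrected intake; negative values are passed through with a
#'   warning.
#' @export
corrected_intake <- function(X, maintenance = 0, mobilization = 0,
                             mode = c("total", "minus_maintenance",
                                      "minus_maintenance_plus_mobilization")) {
  mode <- match.arg(mode)
  stopifnot(all(X >= 0))
  out <- switch(mode,
                total = X,
                minus_maintenance = X - maintenance,
                minus_maintenance_plus_mobilization =
                  X - maintenance + pmax(0, -mobilization))
  if (any(out < 0))
    warning(sum(out < 0), " corrected intake value(s) are negative",
            call. = FALSE)
  out
}

#' Utilization efficiency of a broken-line fit
#'
#' Efficiency is the ratio plateau / breakpoint of a linear-plateau fit of
#' deposition against (corrected) intake: the deposition attained at the
#' requirement divided by the intake needed to attain it.
#'
#' @param fit A [fit_broken_line()] result, or a list with elements
#'   `plateau` and `breakpoint`.
#' @return The efficiency as a fraction.
#' @export
broken_line_efficiency <- function(fit) {
  stopifnot(is.finite(fit$plateau), is.finite(fit$breakpoint),
            fit$breakpoint > 0)
  fit$plateau / fit$breakpoint
}

#' Efficiency suite under the three supply corrections
#'
#' Fits the broken line of deposition `Y` against intake `X` under each of
#' the three supply corrections of [corrected_intake()] and reports the
#' three efficiencies.
#'
#' @param data Data frame with columns `X`, `Y` and (for the mobilization
#'   correction) `arg_mobilization`, all standardized to mg/kg^0.67/d.
#' @param maintenance Maintenance intake, mg/kg^0.67/d.
#' @return A list of class `efficiency_report` with `k_total`,
#'   `k_intake_minus_maintenance`, `k_intake_minus_maint_plus_mob`, and
#'   the three underlying `broken_line_fit` objects in `fits`.
#' @export
efficiency_suite <- function(data, maintenance) {
  stopifnot(all(c("X", "Y") %in% names(data)))
  mob <- if ("arg_mobilization" %in% names(data)) data$arg_mobilization
  else rep(0, nrow(data))
  modes <- c("total", "minus_maintenance",
             "minus_maintenance_plus_mobilization")
  fits <- lapply(modes, function(m) {
    xc <- corrected_intake(data$X, maintenance, mob, mode = m)
    fit_broken_line(xc, data$Y)
  })
  names(fits) <- modes
  eff <- vapply(fits, broken_line_efficiency, numeric(1))
  structure(list(k_total = eff[["total"]],
                 k_intake_minus_maintenance = eff[["minus_maintenance"]],
                 k_intake_minus_maint_plus_mob =
                   eff[["minus_maintenance_plus_mobilization"]],
                 fits = fits),
            class = "efficiency_report")
}

#' Per-treatment requirement statistic
#'
#' For each treatment, the arginine available above maintenance per gram of
#' egg mass produced:
#' `Req = (arg_intake - m * (body_weight/1000)^0.67) / egg_mass`
#' in mg arginine per g egg, with intake in mg/bird/d, body weight in g and
#' egg mass in g/bird/d.
#'
#' @param summary Data frame with columns `treatment`, `arg_intake`,
#'   `body_weight` (g) and `egg_mass`; typically the output of
#'   [summarize_treatments()].  An `egg_production` column (fraction or
#'   percent) is carried through, as percent, when present.
#' @param m Maintenance coefficient, mg/kg^0.67/d (default 90).
#' @param exponent Allometric exponent (default 0.67).
#' @return Data frame with `treatment`, `req_raw` (unrounded, mg/g), `req`
#'   (rounded to integer mg/g) and, when available, `egg_production` in
#'   percent.  Treatments with zero egg mass are dropped with a warning.
#' @export
treatment_requirement <- function(summary, m = 90, exponent = 0.67) {
  stopifnot(all(c("treatment", "arg_intake", "body_weight", "egg_mass")
                %in% names(summary)))
  zero <- summary$egg_mass <= 0
  if (any(zero)) {
    warning("dropping ", sum(zero),
            " treatment(s) with zero egg mass: requirement undefined",
            call. = FALSE)
    summary <- summary[!zero, , drop = FALSE]
  }
  maint <- m * (summary$body_weight / 1000)^exponent
  req_raw <- (summary$arg_intake - maint) / summary$egg_mass
  out <- data.frame(treatment = summary$treatment,
                    req_raw = req_raw,
                    req = round(req_raw))
  if ("egg_production" %in% names(summary)) {
    ep <- summary$egg_production
    out$egg_production <- ifelse(ep <= 1, ep * 100, ep)
  }
  out
}

#' Egg-mass requirement coefficient from the production/requirement curve
#'
#' Fits a broken line of egg production (%) against the per-treatment
#' requirement statistic Req (mg/g): production rises with Req up to a
#' breakpoint and plateaus beyond it.  The breakpoint is the egg-mass
#' requirement coefficient `q` (mg arginine per g egg) used in the
#' factorial intake model.
#'
#' @param reqs Data frame with columns `req_raw` (or `req`) and
#'   `egg_production` (percent), as from [treatment_requirement()].
#' @return A list with `q` (the breakpoint, mg/g) and the underlying
#'   `broken_line_fit`.
#' @export
egg_mass_coefficient <- function(reqs) {
  x <- if ("req_raw" %in% names(reqs)) reqs$req_raw else reqs$req
  stopifnot(!is.null(x), "egg_production" %in% names(reqs))
  if (length(x) < 4)
    stop("need at least 4 treatments with a defined requirement",
         call. = FALSE)
  fit <- fit_broken_line(x, reqs$egg_production)
  if (!fit$identified)
    warning("egg-mass coefficient not identified: breakpoint at grid ",
            "boundary or zero slope", call. = FALSE)
  list(q = fit$breakpoint, fit = fit)
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("Utilization efficiency: total %.2f | -maintenance %.2f | -maintenance+mobilization %.2f\n",
              x$k_total, x$k_intake_minus_maintenance,
              x$k_intake_minus_maint_plus_mob))
  invisible(x)
}
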