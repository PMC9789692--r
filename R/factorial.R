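#' Factorial intake model
#'
#' Additive requirement model for daily amino-acid intake:
#' `DAI (mg/bird/d) = m * BW^0.67 + q * min(EM, em_plateau)` with body
#' weight `BW` in kg and egg mass `EM` in g/bird/d.  The egg-mass term is
#' capped at `em_plateau` to avoid overestimating intake at high output.
#' Defaults parameterize the arginine model for laying Japanese quail:
#' maintenance 90 mg/kg^0.67, egg-mass coefficient 25 mg/g, error band
#' +/- 12 mg/bird/d, plateau 11 g/d.
#'
#' @param m Maintenance coefficient, mg per kg metabolic weight per day.
#' @param q Egg-mass coefficient, mg per g egg.
#' @param error_band Expected prediction error band, mg/bird/d.
#' @param em_plateau Egg mass above which the output term is capped, g/d.
#' @param exponent Allometric exponent (default 0.67).
#' @return An object of class `factorial_model`.
#' @export
factorial_model <- function(m = 90, q = 25, error_band = 12,
                            em_plateau = 11, exponent = 0.67) {
  stopifnot(m > 0, q > 0, error_band >= 0, em_plateau > 0)
  structure(list(m = m, q = q, error_band = error_band,
                 em_plateau = em_plateau, exponent = exponent),
            class = "factorial_model")
}

#' Predict daily intake from the factorial model
#'
#' @param model A [factorial_model()].
#' @param body_weight Body weight, kg (> 0); vectorized.
#' @param egg_mass Egg mass, g/bird/d (>= 0); vectorized.
#' @return Predicted daily intake, mg/bird/d (unrounded).
#' @examples
#' predict_intake(factorial_model(), 0.180, 11)  # ~304 mg/bird/d
#' @export
predict_intake <- function(model, body_weight, egg_mass) {
  stopifnot(inherits(model, "factorial_model"),
            all(body_weight > 0), all(egg_mass >= 0))
  model$m * body_weight^model$exponent +
    model$q * pmin(egg_mass, model$em_plateau)
}

#' Validate the factorial model against observed intakes
#'
#' Computes per-row prediction errors (observed - predicted) and flags rows
#' whose absolute error exceeds the model's error band.
#'
#' @param model A [factorial_model()].
#' @param rows Data frame with columns `body_weight` (kg), `egg_mass`
#'   (g/d) and `observed_intake` (mg/bird/d); a `source` column is carried
#'   through when present.
#' @return The rows with `predicted`, `error` and `outside_band` appended.
#' @export
validate_intake_model <- function(model, rows) {
  stopifnot(all(c("body_weight", "egg_mass", "observed_intake")
                %in% names(rows)))
  out <- rows
  out$predicted <- predict_intake(model, rows$body_weight, rows$egg_mass)
  out$error <- rows$observed_intake - out$predicted
  out$outside_band <- abs(out$error) > model$error_band
  out
}

#' Arginine:lysine intake ratio
#'
#' Ratio of the factorial-model arginine intake to the factorial-model
#' lysine intake at the same body weight and egg mass.  The default lysine
#' model uses maintenance 136 mg/kg^0.67 and egg-mass coefficient
#' 21 mg/g.
#'
#' @param model Arginine [factorial_model()].
#' @param lys_model Lysine [factorial_model()].
#' @param body_weight Body weight, kg.
#' @param egg_mass Egg mass, g/d.
#' @return The dimensionless Arg:Lys intake ratio.
#' @export
arg_lys_ratio <- function(model = factorial_model(),
                          lys_model = factorial_model(m = 136, q = 21,
                                                      error_band = 0),
                          body_weight, egg_mass) {
  predict_intake(model, body_weight, egg_mass) /
    predict_intake(lys_model, body_weight, egg_mass)
}

#' @export
print.factorial_model <- function(x, ...) {
  cat(sprintf("Factorial intake model: DAI = %g * BW^%g + %g * min(EM, %g) +/- %g mg/bird/d\n",
              x$m, x$exponent, x$q, x$em_plateau, x$error_band))
  invisible(x)
}
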