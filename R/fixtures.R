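#' Published treatment means of the arginine laying trial
#'
#' Treatment-level means of the seven-diet arginine trial in laying
#' Japanese quail: dietary level (g/kg), feed intake (g/bird/d), arginine
#' intake (mg/bird/d), egg production (%), egg weight (g), egg mass
#' (g/bird/d), feed efficiency (g egg per g feed), arginine deposition in
#' egg (mg/bird/d), body weight (g), body-weight change over the 28-d
#' collection window (g) and arginine mobilization (mg/bird/d).
#'
#' @return A data frame with one row per treatment D1-D7.
#' @export
quail_treatment_means <- function() {
  path <- system.file("extdata", "treatment_means.csv",
                      package = "quailarg", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Literature validation rows for the factorial intake model
#'
#' Body weight (kg), daily egg mass (g/bird/d) and observed daily arginine
#' intake (mg/bird/d) from published quail studies used to validate the
#' factorial model.  Where a study did not report body weight, rows at
#' assumed weights of 0.170, 0.180 and 0.190 kg are included.
#'
#' @return A data frame with columns `source`, `body_weight`, `egg_mass`,
#'   `observed_intake`.
#' @export
quail_validation_rows <- function() {
  path <- system.file("extdata", "literature_validation.csv",
                      package = "quailarg", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Synthetic per-bird trial reconstructed from treatment means
#'
#' Builds a 49-bird trial table in the [read_trial()] schema whose raw
#' columns equal the published treatment means within each treatment
#' (every bird in a treatment carries the treatment-mean feed intake, egg
#' production, egg weight and body weights).  This is a synthetic
#' stand-in for the deposited per-bird data: treatment means of derived
#' variables are reproduced exactly, within-treatment variation is not.
#'
#' @param birds_per_treatment Birds per treatment (default 7).
#' @return A data frame of per-bird records.
#' @export
synthetic_trial_from_means <- function(birds_per_treatment = 7L) {
  tm <- quail_treatment_means()
  rows <- lapply(seq_len(nrow(tm)), function(i) {
    data.frame(observation = NA_integer_,
               cage = NA_integer_,
               treatment = tm$treatment[i],
               replicate = seq_len(birds_per_treatment),
               arg_level = tm$arg_level[i],
               feed_intake = tm$feed_intake[i],
               egg_production = tm$egg_production[i] / 100,
               egg_weight = tm$egg_weight[i],
               bw_initial = tm$body_weight[i] - tm$bw_change[i] / 2,
               bw_final = tm$body_weight[i] + tm$bw_change[i] / 2)
  })
  out <- do.call(rbind, rows)
  out$observation <- seq_len(nrow(out))
  out$cage <- out$observation
  out$bird_id <- paste(out$treatment, out$replicate, sep = "_")
  out
}

#' Standardized treatment-mean response observations
#'
#' Converts the published treatment means into standardized `(X, Y)`
#' response observations: arginine intake and deposition per kg metabolic
#' body weight (mg/kg^0.67/d), using each treatment's reported body
#' weight.
#'
#' @param exponent Allometric exponent (default 0.67).
#' @return Data frame with `treatment`, `X`, `Y`, `body_weight` (kg) and
#'   `arg_mobilization` (standardized, mg/kg^0.67/d).
#' @export
standardized_treatment_means <- function(exponent = 0.67) {
  tm <- quail_treatment_means()
  data.frame(treatment = tm$treatment,
             X = standardize_metabolic(tm$arg_intake, tm$body_weight,
                                       exponent),
             Y = standardize_metabolic(tm$arg_deposition, tm$body_weight,
                                       exponent),
             body_weight = tm$body_weight / 1000,
             arg_mobilization = standardize_metabolic(
               tm$arg_mobilization, tm$body_weight, exponent))
}
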