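#' Configuration for a synthetic laying trial
#'
#' Describes a completely randomized trial of single-bird cages across
#' increasing dietary arginine levels whose egg-arginine-deposition
#' response follows a known ground-truth curve.  Defaults emulate the
#' study conditions: 7 levels spanning 2.43-14.56 g/kg, 7 birds per
#' level, a saturating feed-intake rule spanning roughly 13-26 g/d, egg
#' weight ramping 5.4-10.9 g across levels, body weight around 171 g, and
#' body-weight change ramping from about -35 g (deficient diets) to +5 g
#' over a 28-day collection window.
#'
#' @param arg_levels Dietary arginine levels, g/kg, strictly increasing.
#' @param birds_per_level Birds (replicates) per level, >= 1.
#' @param true_params Ground-truth response curve on the mg/kg^0.67 scale:
#'   a [saturation_params()] or [monomolecular_params()] object.
#' @param bird_sd SD of the bird-level random shift in the maximum
#'   response, mg/kg^0.67 (>= 0).
#' @param resid_sd SD of the observation noise on deposition,
#'   mg/kg^0.67 (>= 0).
#' @param intake_curve Saturating feed-intake rule: list with `min` and
#'   `max` asymptotic intakes (g/d), exponential `rate` per g/kg, and the
#'   intake noise `sd` (g/d).
#' @param ew_range Egg weight at the lowest level and its asymptote, g.
#'   Egg weight rises monomolecularly between the two at `ew_rate` per
#'   g/kg of dietary arginine, and scales allometrically with each bird's
#'   body weight so that back-solved egg production stays below one for
#'   birds of any size.
#' @param ew_rate Exponential rate of the egg-weight ramp, per g/kg.
#' @param bw_base,bw_sd Mean and SD of bird body weight, g.
#' @param bw_change_range Body-weight change at the lowest and highest
#'   level, g over the collection window.
#' @param composition A [composition_table()] used to back-solve egg
#'   production from the target deposition.
#' @param seed Integer seed making [generate_trial()] deterministic.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(arg_levels = c(2.43, 3.64, 4.85, 6.07,
                                            9.07, 12.13, 14.56),
                             birds_per_level = 7L,
                             true_params = saturation_params(232, 21, 291,
                                                             3.413),
                             bird_sd = 10,
                             resid_sd = 15,
                             intake_curve = list(min = 13, max = 26,
                                                 rate = 0.25, sd = 1),
                             ew_range = c(5.4, 10.9),
                             ew_rate = 0.55,
                             bw_base = 171, bw_sd = 8,
                             bw_change_range = c(-35, 5),
                             composition = composition_table(),
                             seed = 1L) {
  stopifnot(all(diff(arg_levels) > 0), birds_per_level >= 1,
            bird_sd >= 0, resid_sd >= 0, intake_curve$sd >= 0,
            bw_sd >= 0, bw_base > 0)
  structure(list(arg_levels = arg_levels,
                 birds_per_level = as.integer(birds_per_level),
                 true_params = true_params,
                 bird_sd = bird_sd, resid_sd = resid_sd,
                 intake_curve = intake_curve, ew_range = ew_range,
                 ew_rate = ew_rate,
                 bw_base = bw_base, bw_sd = bw_sd,
                 bw_change_range = bw_change_range,
                 composition = composition, seed = as.integer(seed)),
            class = "synthetic_config")
}

eval_true_curve <- function(p, X, rmax_shift = 0) {
  if (inherits(p, "saturation_params")) {
    q <- saturation_params(p$Rmax + rmax_shift, p$Rmin, p$km, p$n)
    eval_saturation(q, X)
  } else {
    q <- monomolecular_params(p$Rmax + rmax_shift, p$Rmin, p$k, p$Xm,
                              form = p$form)
    eval_monomolecular(q, X)
  }
}

#' Generate a synthetic laying trial with known ground truth
#'
#' Draws a complete trial in the per-bird record schema of [read_trial()].
#' For each bird: feed intake follows the saturating intake rule plus
#' Gaussian noise; the target deposition on the standardized scale is the
#' ground-truth curve evaluated at the realized intake, with a bird-level
#' random shift of the maximum response and Gaussian residual noise; egg
#' weight and body-weight change follow level-dependent ramps; egg
#' production is back-solved so that deriving the records with the same
#' composition table reproduces the target deposition exactly (up to the
#' injected noise).  Egg production is clipped into `[0, 1]` with a
#' warning if the noise drives it outside.
#'
#' @param config A [synthetic_config()].
#' @return A list with `records` (data frame in the trial schema),
#'   `truth` (generating parameters, per-bird random effects, and the
#'   realized standardized `X` and target `Y`), and the `config`.
#'   Deterministic given `config$seed`.
#' @export
generate_trial <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  lv <- config$arg_levels
  nb <- config$birds_per_level
  comp <- config$composition
  span <- diff(range(lv))
  rows <- vector("list", length(lv) * nb)
  bird_effects <- numeric(0)
  Xs <- Ys <- numeric(0)
  clipped <- 0L
  obs <- 0L
  for (i in seq_along(lv)) {
    l <- lv[i]
    frac <- (l - lv[1]) / span
    fi_mean <- config$intake_curve$max -
      (config$intake_curve$max - config$intake_curve$min) *
      exp(-config$intake_curve$rate * (l - lv[1]))
    ew_level <- config$ew_range[2] - diff(config$ew_range) *
      exp(-config$ew_rate * (l - lv[1]))
    dbw <- config$bw_change_range[1] + diff(config$bw_change_range) * frac
    for (j in seq_len(nb)) {
      obs <- obs + 1L
      bw_mid <- config$bw_base + stats::rnorm(1, 0, config$bw_sd)
      fi <- max(0.1, fi_mean + stats::rnorm(1, 0, config$intake_curve$sd))
      b_j <- stats::rnorm(1, 0, config$bird_sd)
      met <- (bw_mid / 1000)^0.67
      ew <- ew_level * (bw_mid / config$bw_base)^0.67
      X <- fi * l / met
      Y <- eval_true_curve(config$true_params, X, b_j) +
        stats::rnorm(1, 0, config$resid_sd)
      dep <- Y * met
      em <- dep / comp$egg_arg_coefficient
      ep <- em / ew
      if (ep < 0 || ep > 1) {
        clipped <- clipped + 1L
        ep <- min(1, max(0, ep))
      }
      bird_effects <- c(bird_effects, b_j)
      Xs <- c(Xs, X); Ys <- c(Ys, Y)
      rows[[obs]] <- data.frame(
        observation = obs, cage = obs,
        treatment = sprintf("D%d", i), replicate = j,
        arg_level = l, feed_intake = fi, egg_production = ep,
        egg_weight = ew, bw_initial = bw_mid - dbw / 2,
        bw_final = bw_mid + dbw / 2)
    }
  }
  if (clipped > 0)
    warning(clipped, " egg production value(s) clipped into [0, 1]",
            call. = FALSE)
  records <- do.call(rbind, rows)
  records$bird_id <- paste(records$treatment, records$replicate, sep = "_")
  names(bird_effects) <- records$bird_id
  list(records = records,
       truth = list(params = config$true_params,
                    bird_effects = bird_effects,
                    X = Xs, Y = Ys),
       config = config)
}
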