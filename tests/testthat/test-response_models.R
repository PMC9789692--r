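test_that("saturation curve evaluates to its defining landmarks", {
  p <- m2_params()
  expect_equal(eval_saturation(p, 291), (232 + 21) / 2)
  expect_equal(eval_saturation(p, 0), 21)
  # direct evaluation at the D5 standardized intake (frozen oracle value)
  expect_equal(eval_saturation(p, 685.6), 221.2519, tolerance = 1e-4)
  # approaches Rmax from below
  expect_lt(eval_saturation(p, 1e6), 232)
  expect_equal(eval_saturation(p, 1e6), 232, tolerance = 1e-3)
})

test_that("shifted monomolecular curve anchors at (Xm, -Rmin) and rises to Rmax", {
  p <- m1_params()
  expect_equal(eval_monomolecular(p, 90), -11)
  expect_equal(eval_monomolecular(p, 1e5), 249, tolerance = 1e-6)
  # frozen direct evaluation at the D5 standardized intake
  expect_equal(eval_monomolecular(p, 685.6), 224.0321, tolerance = 1e-4)
  # the printed form is kept verbatim and is non-increasing
  pp <- m1_params(form = "printed")
  expect_equal(eval_monomolecular(pp, 90), 249)
  xs <- seq(0, 2000, by = 50)
  expect_true(all(diff(eval_monomolecular(pp, xs)) <= 0))
})

test_that("both response families are strictly increasing over parameter sweeps", {
  set.seed(13)
  xs <- seq(0, 2000, length.out = 200)
  for (i in 1:15) {
    p <- saturation_params(Rmax = runif(1, 50, 400),
                           Rmin = runif(1, 0, 40),
                           km = runif(1, 50, 800), n = runif(1, 0.5, 6))
    expect_true(all(diff(eval_saturation(p, xs)) >= 0))
    expect_true(all(efficiency_curve(p, xs[xs > 0]) > 0))
    m <- monomolecular_params(Rmax = runif(1, 50, 400),
                              Rmin = runif(1, 0, 40),
                              k = runif(1, 0.001, 0.02),
                              Xm = runif(1, 0, 200))
    expect_true(all(diff(eval_monomolecular(m, xs)) >= 0))
    expect_true(all(efficiency_curve(m, xs) > 0))
  }
})

test_that("efficiency curve matches central differences and decays", {
  set.seed(21)
  p <- m2_params(); m <- m1_params()
  xs <- runif(50, 10, 1500)
  h <- 1e-4
  num_sat <- (eval_saturation(p, xs + h) - eval_saturation(p, xs - h)) /
    (2 * h)
  num_mono <- (eval_monomolecular(m, xs + h) -
                 eval_monomolecular(m, xs - h)) / (2 * h)
  expect_rel_equal(efficiency_curve(p, xs), num_sat, rel = 1e-6)
  expect_rel_equal(efficiency_curve(m, xs), num_mono, rel = 1e-6)
  expect_lt(efficiency_curve(p, 1e7), 1e-10)
  # monomolecular marginal efficiency at the maintenance anchor
  expect_equal(efficiency_curve(m, 90), 0.003934 * 260, tolerance = 1e-10)
})

test_that("landmark intakes match numeric optimization oracles", {
  p <- m2_params()
  expect_equal(round(maintenance_intake(p)$per_kg), 144)
  expect_equal(round(intake_at_max_slope(p)), 244)
  expect_equal(round(intake_at_max_efficiency(p)), 377)

  # brute-force oracles
  o_slope <- stats::optimize(function(x) efficiency_curve(p, x),
                             c(1, 3000), maximum = TRUE, tol = 1e-8)$maximum
  o_eff <- stats::optimize(function(x) (eval_saturation(p, x) - p$Rmin) / x,
                           c(1, 5000), maximum = TRUE, tol = 1e-8)$maximum
  expect_lt(abs(intake_at_max_slope(p) - o_slope), 0.1)
  expect_lt(abs(intake_at_max_efficiency(p) - o_eff), 0.1)

  # limits and degenerate orders
  expect_equal(intake_at_max_efficiency(saturation_params(100, 1, 100, 2)),
               100)
  p_big <- saturation_params(232, 21, 291, 200)
  expect_equal(intake_at_max_slope(p_big), 291, tolerance = 0.01)
  p_low <- saturation_params(232, 21, 291, 0.9)
  expect_error(intake_at_max_slope(p_low), "n")
  expect_error(intake_at_max_efficiency(p_low), "n")
})

test_that("maintenance intake scales with metabolic weight and handles edge cases", {
  m <- m1_params()
  mi <- maintenance_intake(m, body_weight = 0.180)
  expect_equal(mi$per_kg, 90)
  expect_equal(round(mi$per_bird, 1), 28.5)
  # Rmin -> Rmax limit collapses the saturation maintenance to km
  near <- saturation_params(100, 100 * (1 - 1e-9), 250, 3)
  expect_equal(maintenance_intake(near)$per_kg, 250, tolerance = 1e-6)
  expect_warning(z <- maintenance_intake(saturation_params(100, 0, 250, 3)),
                 "Rmin")
  expect_equal(z$per_kg, 0)
  # the saturation maintenance intake satisfies the harmonic-mean identity
  p <- m2_params()
  xm <- maintenance_intake(p)$per_kg
  expect_equal(eval_saturation(p, xm),
               2 * p$Rmin * p$Rmax / (p$Rmin + p$Rmax), tolerance = 1e-10)
})

test_that("noiseless pipelines recover the generating curves (oracle equivalence)", {
  # saturation: all four parameters to >= 6 significant digits
  cfg <- noiseless_sat_config(seed = 7)
  d <- derive_birds(generate_trial(cfg)$records, cfg$composition)
  f <- fit_response(d, "saturation")
  expect_rel_equal(unlist(unclass(f$params)),
                   c(232, 21, 291, 3.413), rel = 1e-7)
  expect_equal(f$r2_adj, 1, tolerance = 1e-10)

  # monomolecular: anchored at the generating Rmin, all four recovered
  cfgm <- noiseless_mono_config()
  dm <- derive_birds(generate_trial(cfgm)$records, cfgm$composition)
  fm <- fit_response(dm, "monomolecular", Rmin_fixed = 11)
  expect_rel_equal(unlist(unclass(fm$params)[c("Rmax", "Rmin", "k", "Xm")]),
                   c(249, 11, 0.003934, 90), rel = 1e-6)

  # the (Rmin, Xm) ridge: any anchor reproduces the identical curve
  fm0 <- fit_response(dm, "monomolecular", Rmin_fixed = 0)
  xs <- seq(100, 1500, length.out = 40)
  expect_rel_equal(eval_monomolecular(fm0$params, xs),
                   eval_monomolecular(fm$params, xs), rel = 1e-8)
  expect_false(isTRUE(all.equal(fm0$params$Xm, fm$params$Xm)))
})

test_that("response fitting guards its preconditions", {
  d <- data.frame(X = rep(5, 10), Y = rnorm(10))
  expect_error(fit_response(d, "saturation"), "spread")
  d2 <- data.frame(X = 1:4, Y = 1:4)
  expect_error(fit_response(d2, "saturation"), "observations")
})

test_that("two-stage random-maximum mode shrinks bird offsets and keeps the curve", {
  cfg <- synthetic_config(bird_sd = 12, resid_sd = 8, seed = 31)
  d <- derive_birds(suppressWarnings(generate_trial(cfg))$records,
                    cfg$composition)
  fr <- fit_response(d, "saturation", random_rmax = TRUE)
  ff <- fit_response(d, "saturation")
  expect_length(fr$bird_effects, 49)
  # shrunk offsets correlate with the simulated bird effects
  truth <- suppressWarnings(generate_trial(cfg))$truth$bird_effects
  expect_gt(cor(fr$bird_effects[names(truth)], truth), 0.3)
  expect_equal(fr$params$km, ff$params$km, tolerance = 0.15)
})

test_that("broken-line fits recover exact piecewise data and flag degeneracy", {
  set.seed(2)
  X <- runif(49, 100, 1000)
  Y <- 225 - 0.53 * pmax(0, 484 - X)
  b <- fit_broken_line(X, Y)
  expect_rel_equal(c(b$plateau, b$slope, b$breakpoint),
                   c(225, 0.53, 484), rel = 1e-6)
  expect_true(b$identified)

  # pure plateau: slope ~ 0, breakpoint pinned to the grid edge, flagged
  bp <- suppressWarnings(fit_broken_line(X, rep(200, length(X))))
  expect_lt(abs(bp$slope), 1e-8)
  expect_false(bp$identified)

  expect_error(fit_broken_line(rep(3, 10), rnorm(10)), "degenerate")
  expect_error(fit_broken_line(1:3, 1:3), "4 observations")
})

test_that("landmark ordering holds across the admissible parameter space", {
  set.seed(5)
  # max-slope intake always precedes km and the max-efficiency intake;
  # km precedes the max-efficiency intake only once n exceeds 2
  # ((n - 1)^(1/n) < 1 for 1 < n < 2)
  for (i in 1:25) {
    p <- saturation_params(Rmax = runif(1, 100, 400),
                           Rmin = runif(1, 0.5, 50),
                           km = runif(1, 100, 600),
                           n = runif(1, 1.05, 8))
    expect_lt(intake_at_max_slope(p), p$km)
    expect_lt(intake_at_max_slope(p), intake_at_max_efficiency(p))
    if (p$n > 2) expect_gt(intake_at_max_efficiency(p), p$km)
  }
})
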