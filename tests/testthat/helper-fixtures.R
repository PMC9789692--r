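# published fitted parameter sets used as golden inputs
m2_params <- function() saturation_params(232, 21, 291, 3.413)
m1_params <- function(form = "shifted")
  monomolecular_params(249, 11, 0.003934, 90, form = form)

# fully deterministic noiseless trial configurations
noiseless_sat_config <- function(seed = 7)
  synthetic_config(bird_sd = 0, resid_sd = 0, seed = seed)

noiseless_mono_config <- function(seed = 3)
  synthetic_config(true_params = m1_params(),
                   bird_sd = 0, resid_sd = 0, bw_sd = 0,
                   ew_range = c(5.4, 12.5),
                   intake_curve = list(min = 13, max = 26,
                                       rate = 0.25, sd = 0),
                   seed = seed)

# standardized X design of a deterministic trial, for regression studies
trial_x_design <- function() {
  cfg <- noiseless_sat_config(seed = 1)
  derive_birds(suppressWarnings(generate_trial(cfg))$records,
               cfg$composition)$X
}

expect_rel_equal <- function(actual, expected, rel = 1e-6) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), rel)
}
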