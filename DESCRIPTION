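Package: quailarg
Title: Arginine Intake-Response Modelling for Laying Japanese Quail
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to derive arginine intake, egg deposition and body
    mobilization from laying-trial records, fit four-parameter
    monomolecular and saturation-kinetics intake-response curves on a
    metabolic body-weight scale, estimate maintenance and egg-mass
    requirements via broken-line (linear-plateau) regression, quantify
    utilization efficiency with maintenance and mobilization corrections,
    and parameterize and validate a factorial intake model of the form
    daily intake = m * BW^0.67 + q * EM.  Includes a synthetic-trial
    generator with known ground truth for parameter-recovery studies,
    pre-modelling screening statistics (orthogonal polynomial contrasts
    over unequally spaced dose levels, an outlier screen), and model
    assessment statistics (adjusted R-squared, BIC, residual-bias
    regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
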