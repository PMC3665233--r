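Package: graytvc
Title: Piecewise-Constant Time-Varying Coefficient Survival Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Cox proportional-hazards models with Efron handling of
    tied failure times and Gray's piecewise-constant time-varying
    coefficient (PC-TVC) model, in which each log hazard ratio is a step
    function over intervals between knots placed at observed failure
    times and is estimated by maximising a penalized partial likelihood
    with a first-difference roughness penalty.  Smoothing is controlled
    by effective degrees of freedom.  Includes Wald tests of overall
    covariate effect and of proportional hazards, Kaplan-Meier and
    weighted logrank (logrank, Tarone-Ware) comparisons, two-stage
    covariate selection (univariable screen then forward selection),
    goodness-of-fit via jackknife pseudo-observations with lowess
    summaries, multiple imputation with Rubin's-rules pooling, and a
    synthetic right-censored cohort generator with piecewise-constant
    hazards and time-varying effects for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    survival,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
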