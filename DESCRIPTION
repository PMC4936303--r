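Package: nldecomp
Title: Nonlinear Blinder-Oaxaca and Fairlie Decomposition of Binary
    Outcome Gaps in Complex Survey Data
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes group differences in a binary outcome (such as the
    wealth-based gap in facility-based delivery coverage) into explained
    and unexplained portions using group-specific survey-weighted logit
    models with primary-sampling-unit cluster-robust standard errors.
    Implements the aggregate nonlinear Blinder-Oaxaca decomposition and
    the Fairlie detailed decomposition with rank matching on predicted
    probabilities, repeated subsampling of the larger group, and
    randomised covariate orderings.  Includes a synthetic generator for
    DHS-like stratified two-stage cluster samples with a principal
    component asset index, descriptive table utilities with weighted
    proportion tests, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
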