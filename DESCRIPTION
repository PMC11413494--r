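Package: escapekin
Title: Escape-Jump Kinematics and Multivariate Performance Inference for
    Rodent Strike-Simulator Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs jump kinematics (take-off velocity, angle and jump
    height) from horizontal displacement and airborne time recorded in
    simulated predator-strike trials, applies the trial censoring and
    exclusion rules used in field studies of rodent escape behaviour,
    size-corrects performance metrics by allometric log-log regression, and
    runs the inference layer: distance-based PERMANOVA with a permutation
    null, one-way linear models with Tukey HSD pairwise comparisons and
    compact letter displays, and logistic regression of escape mode on
    reaction time. A synthetic trial generator emulates species-specific
    jump propensities, timing and performance distributions, frame-rate
    quantization and tape-measure rounding, so the full pipeline runs and is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
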