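Package: placebonirs
Title: Placebo and Nocebo Analysis of Differential-Conditioning fNIRS Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cue-conditioned placebo and nocebo effects measured
    with multi-distance functional near-infrared spectroscopy (fNIRS). Generates
    differential-conditioning trial schedules (low/high-frequency auditory cues paired
    with low/high-intensity electrical shocks), simulates multi-channel hemoglobin
    time series with shared systemic physiology and known ground truth, removes
    systemic noise from long (composite) channels by projecting out principal
    components of the short non-cerebral channels, computes cue-locked effect sizes
    in dorsolateral prefrontal cortex regions of interest, derives visual-analog-scale
    pain reduction (placebo) and enhancement (nocebo) indices, and runs the associated
    inferential battery: factorial ANOVA with Bonferroni post hoc tests, per-group
    Pearson correlations with Holm correction, forced-entry and stepwise multiple
    regression, Mann-Whitney U tests with rank-based effect sizes, and distributional
    assumption checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    MASS,
    nortest,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
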