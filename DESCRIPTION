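Package: vtacuity
Title: Simulation and Analysis of Visuo-Tactile Temporal Psychophysics
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying temporal acuity across the visual and
    tactile modalities with two classic paradigms: categorization of the
    rate of temporally jittered pulse trains, and two-interval
    forced-choice (2IFC) detection of a brief unfilled gap between two
    pulses.  Provides generators for jittered pulse-train stimuli and
    full experiment schedules, a configurable synthetic observer that
    produces trial-level responses with realistic modality asymmetries,
    nonparametric sensitivity (A) and decision-criterion (b) estimation,
    maximum-likelihood 2AFC psychometric-function fitting with
    gap-detection thresholds at the d-prime = 1 criterion and bootstrap
    standard errors, and the repeated-measures inference used to compare
    modalities (criterion-vs-neutral tests, simple effects,
    within-subject error bars, and unimodal-bimodal accuracy
    regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
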