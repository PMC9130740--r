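Package: nbrlifespan
Title: Lifespan Analysis of Negative BOLD Responses with Data-Driven
    Haemodynamic Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-related fMRI analysis of positive and negative BOLD
    responses (PBR/NBR) across the adult lifespan. Provides a synthetic
    BOLD data generator that emulates a rapid audiovisual sensorimotor
    paradigm with ageing haemodynamic-response trajectories, first-level
    GLM fitting with canonical double-gamma or data-driven kernels, FIR
    deconvolution of region haemodynamic responses, subject-specific
    cubic-ROI and spatial-extent statistics, framewise-displacement
    summaries, and group-level lifespan statistics (decile contrasts,
    age-covariate maps, ANOVA, correlations, nested-regression tests).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
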