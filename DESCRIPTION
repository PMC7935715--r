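Package: ffasim
Title: Simulation and Analytical Validation of Fetal Fraction Amplification
    for WGS-Based Noninvasive Prenatal Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale reimplementation of the computational core of an
    analytical validation of fetal fraction amplification (FFA) in
    whole-genome-sequencing based noninvasive prenatal screening (NIPS).
    Simulates two-compartment (maternal/fetal) cell-free DNA cohorts over a
    binned scaled genome, applies in-silico fragment-length size selection
    with a closed-form fetal-fraction gain law, estimates fetal fraction
    from binned read depth (chrY, aneuploid-region deviation, and a ridge
    regression on autosomal bins), screens for aneuploidies, microdeletions
    and sex chromosome abnormalities via reference-cohort z-scores and a
    two-dimensional chrX/chrY analysis, quantifies screening performance
    with a two-phase MCMC-trained ROC model, and models sex-call accuracy
    with a normal/beta mixture and optimized calling threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    glmnet,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
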