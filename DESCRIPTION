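Package: vascelast
Title: Model-Based Vascular Elastography for Small-Animal Carotid Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative ultrasound elastography of the mouse carotid artery.
    Simulates annular vessel phantoms loaded by luminal pressure, solves the
    plane-strain nearly incompressible finite-element forward problem, tracks
    wall displacements on simulated radio-frequency (RF) echo frames by
    normalized cross-correlation block matching, and reconstructs the regional
    Young's modulus map by a Tikhonov-regularized Gauss-Newton inversion.
    Also computes Doppler-derived hemodynamic indices (volume flow, wall shear
    stress, resistive and pulsatility indices, carotid strain), converts serial
    histology compartment areas into compartment volumes and intima/media
    ratios, and runs the cohort-level statistics (group summaries, t tests,
    one-way ANOVA with post hoc comparisons, modulus-remodeling correlations)
    used in low-flow carotid ligation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
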