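Package: scanqc
Title: Semi-Automatic Quality Control for Multi-Site MRI Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for semi-automatic quality control (QC) of multi-centre
    magnetic resonance imaging studies. Computes per-scan image-quality
    features for structural (T1-weighted), functional (4D BOLD) and diffusion
    MRI across five feature domains (motion, noise, inhomogeneity, asymmetry,
    descriptives); ranks scans by summed site-wise Z-score deviation and flags
    a top fraction for blinded visual review alongside matched random inliers;
    and quantifies feature informativeness against ordinal visual labels with
    proportional-odds regression, backward AIC elimination and covariate
    screens. A fully parametric multi-site phantom generator (tissue-contrast
    volumes, motion traces, diffusion signals from known tensors, injected
    artifacts with ground-truth labels) makes every stage testable without any
    image download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
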