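Package: ovispec
Title: Vis-SWNIR Hyperspectral Transmission Chemometrics for Egg Fertility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native chemometric pipeline for discriminating
    fertile from infertile unincubated chicken eggs using visible/short-wave
    near-infrared (500-950 nm) transmission hyperspectral images. Covers
    hypercube segmentation and relative-transmittance extraction, spectral
    pretreatments (normalization, SNV, MSC, baseline correction,
    Savitzky-Golay derivatives), Hotelling T-squared outlier screening,
    SIMCA classification with per-wavelength discrimination power, LDA/QDA
    in principal-component score space, single-hidden-layer neural networks
    with topology search and sensitivity analysis, discrimination-power
    waveband selection, spectral-difference features, and a synthetic
    hypercube generator so the whole pipeline is testable without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    MASS,
    nnet,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
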