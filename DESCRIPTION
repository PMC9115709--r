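Package: spheroidperm
Title: Drug Permeability Analysis and QSAR Modelling for 3D Tumor Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for drug-permeability screening in three-dimensional
    multicellular tumor spheroids. Converts ATP-luminescence viability readouts into
    per-drug efficacies and permeability values (PV), evaluates drug-likeness rules
    (Lipinski Rule of Five, Ghose filter, Veber's rule, unweighted QED), predicts
    PAMPA membrane permeability from physicochemical descriptors, stratifies PVs by
    rule compliance with two-sample tests, and fits a QSAR multiple linear regression
    of PV on nine molecular descriptors with forward stepwise selection, Pareto
    (80/20) train/validation splitting and k-fold cross-validation. Includes spheroid
    morphometrics (circularity, sphericity index, roundness) from segmented masks and
    a synthetic-data generator emulating the 16-drug, 3-replicate screen design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineOB,
    ChemmineR,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
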