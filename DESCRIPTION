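Package: nmrcal
Title: Chemometric Calibration of Solid-State 13C NMR Spectra of Bee Pollen
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative modeling of bee pollen composition from solid-state
    13C CPMAS NMR spectra. Implements spectral pretreatment (multiplicative
    scatter correction, standard normal variate, mean-centering, ppm-window
    selection), principal component analysis, PLS1 regression with NIPALS,
    leave-one-out cross-validation, variable-importance-in-projection scores,
    bootstrap-stabilized Kennard-Stone calibration/validation splitting in
    PCA score space, and RSEP/RMSE error reporting. Ships a 35-sample
    reference table of bee pollen properties and a Lorentzian/Gaussian
    mixture generator producing realistic synthetic spectra for testing the
    full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
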