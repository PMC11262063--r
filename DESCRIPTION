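Package: sersquant
Title: Multiplex Quantification of Thiols from SERS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric pipeline for simultaneous quantification of four
    malodorous thiols (3M3MH, 2M3MB, 3MH, 2M3MP) from surface-enhanced Raman
    (SERS) spectra. Provides spectral preprocessing (asymmetric least squares
    baseline correction, Savitzky-Golay smoothing and derivatives, vector and
    SNV normalisation), PCA-guided peak selection, univariate and multivariate
    limit-of-detection estimation, PLS-1/PLS-2 calibration with
    leave-one-concentration-out double cross-validation and bootstrap
    out-of-bag validation, MCR-ALS curve resolution, and a synthetic SERS
    spectrum generator (Latin hypercube mixture designs, dilution series,
    batch effects, monolayer competition) for end-to-end validation of the
    workflow.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    signal,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
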