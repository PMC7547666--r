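Package: wavesel
Title: Wavelength Selection for Multivariate Spectroscopic Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for selecting informative wavelengths in quantitative
    vibrational spectroscopy. Provides a NIPALS partial least squares (PLS)
    core with PRESS-based choice of the number of latent variables, Monte
    Carlo cross-validation with block-stratified splits, coefficient-magnitude
    and uninformative-variable-elimination selectors, interval PLS
    (iPLS/FS-iPLS) with interval micro-optimisation, moving-window PLS, and a
    multi-run genetic-algorithm selector with resampled fitness, holdout
    acceptance, co-selection statistics and per-wavelength selection
    probabilities. Includes a synthetic Beer-Lambert spectra generator with a
    ground-truth informative-wavelength mask for method benchmarking, and a
    comparison harness producing per-method calibration reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, jsonlite, stats, utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
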