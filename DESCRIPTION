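Package: thionir
Title: In Situ NIR Chemometrics for Sulfhydryl and Disulfide Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibration and evaluation of near-infrared (NIR) models that
    track free sulfhydryl (SH) and disulfide (SS) content of wheat gluten
    during ultrasound treatment. Implements standard normal variate,
    multiplicative scatter correction and Savitzky-Golay derivative
    preprocessing, NIPALS PLS1 regression with cross-validated component
    selection, exhaustive synergy-interval PLS (Si-PLS) wavelength selection,
    and a PCA-compressed three-layer backpropagation neural network, together
    with the usual calibration/prediction metrics (Rc, Rp, RMSEC, RMSECV,
    RMSEP, RPD). A seeded synthetic-data module emulates the in-situ
    acquisition protocol (power densities, sampling times, triplicate
    spectra, 256 channels over 850-2500 nm) so the full pipeline runs and is
    tested without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
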