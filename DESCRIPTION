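Package: spectraits
Title: Leaf Spectroscopy Reduction and Trait Prediction by Partial Least
    Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduces integrating-sphere leaf radiance measurements to
    absolute reflectance, transmittance and absorbance spectra (white-panel
    normalization, stray-light subtraction, mask correction for small-width
    leaves, split-window Savitzky-Golay smoothing), derives leaf functional
    traits (SLA, LDMC, area-based N and P content, N:P nutrient-limitation
    classes), and predicts traits from spectra with single-response partial
    least squares regression (NIPALS) under leave-one-out validation,
    latent-variable selection by minimum validation RMSE, and iterative
    spectral band selection driven by jackknife t-tests on fold regression
    coefficients. A synthetic-data generator with trait-linked Gaussian
    absorption features and a tunable trait-constituent coupling makes every
    pipeline stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    withr
Config/testthat/edition: 3
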