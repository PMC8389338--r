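Package: esnedge
Title: Edge-of-Chaos Input Representations in Echo State Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates echo state networks driven by images converted to
    multivariate time series, locates the order-chaos transition through the
    maximum Lyapunov exponent, measures the power-law decay exponent of the
    reservoir activity covariance eigenspectrum (plain and cross-validated
    PCA, with and without dynamical noise), relates it to the continuity and
    differentiability bound 1 + 2/d for d-dimensional stimuli, and evaluates
    ridge readouts over the reservoir model space on image classification
    tasks across the order-chaos transition. Includes generators for
    synthetic image ensembles with controlled intrinsic dimension, spectral
    slope and class structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
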