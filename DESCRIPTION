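Package: chromdyn
Title: Chromatin Domain Structure from Subdiffusive Nucleosome Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Polymer model of chromatin domains characterized by a fractal
    dimension, fluctuating in a viscoelastic nuclear medium with power-law
    memory friction.  Provides the closed-form theory for the subdiffusive
    mean-squared displacement (MSD) of single nucleosomes (normal-mode
    variances, Mittag-Leffler mode relaxation, center-of-mass subdiffusion,
    and the short-time asymptotic MSD), an inference pipeline that fits the
    empirical power law MSD(t) = D_app * t^beta to ensemble MSD curves and
    inverts the fitted parameters into domain structure (fractal dimension,
    RMS domain size, relaxation time), an ensemble MSD estimator for
    single-particle tracking data with standard errors, and an exact-covariance
    mode-space simulator that generates synthetic single-nucleosome
    trajectories for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
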