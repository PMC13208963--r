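Package: gidep
Title: Variance and Resolution Analysis for Gradient Insulator-Based Dielectrophoresis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies the sources of variance that limit the resolution of
    gradient insulator-based dielectrophoresis (g-iDEP) separations of
    bioparticles. Provides a parametric two-dimensional model of gated
    insulator microchannels with a finite-volume Laplace solver for the
    electric field and its gradient, a stabilized stationary
    convection-diffusion solver for dielectrophoretic capture with a
    Langevin particle-tracking cross-check, extraction of partial-capture
    transition zones (error-function fits, Gaussian sigma, FWHM, 4-sigma
    resolvability), Monte Carlo propagation of experimental uncertainty
    into onset-voltage distributions for the voltage-sweep method, and
    electrokinetic mobility ratio (EKMr) dynamic-range mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
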