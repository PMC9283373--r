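Package: hlecell
Title: Homeostatic Langevin Dynamics of Adherent Cell Morphology and Motility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the coupled morphological evolution and motility of single
    adherent cells on unpatterned and stripe-patterned rigid substrates using an
    overdamped Langevin extension of the homeostatic ensemble. Cell shapes are
    bicubic spline displacement fields over a triangulated disc; each shape is
    scored by a Gibbs free energy combining stress-fibre chemo-mechanics with 2D
    Ogden passive elasticity of cytoplasm and nucleus. The package provides the
    suspension reference solve, Metropolis Monte Carlo sampling and homeostatic
    temperature calibration, Euler-Maruyama integration of the stochastic shape
    dynamics, a reduced two-variable elliptical cell model, and observables for
    spreading timescales, mean squared displacement, and contact guidance order
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    parallel
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
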