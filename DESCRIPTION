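Package: rheoprony
Title: Prony-Series Viscoelastic Modelling of Denture Adhesives with
    Time-Temperature Superposition and Covariate Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building multi-parameter viscoelastic material models
    of denture adhesive pastes from oscillatory frequency-sweep rheometry.
    Implements the generalized Maxwell (Prony series) relaxation modulus with
    Arrhenius time-temperature superposition, horizontal shift-factor
    estimation and master-curve assembly at a 32 degree Celsius reference,
    constrained (non-negative least squares plus bounded refinement) fitting
    of the discrete relaxation spectrum, a multiple-linear-regression and
    Pearson-correlation screen that decides which physiological covariates
    (temperature, swelling ratio, pH) the material model retains, a
    swelling/pH-indexed parameter surface with log-linear interpolation,
    a synthetic rheometry generator with known ground truth emulating the
    oral-cavity test design, and export of solver-neutral finite-element
    Prony material cards.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
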