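Package: hexakin
Title: Single-Particle Kinetics of Insulin Hexamer Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn TIRF movies of surface-immobilized, fluorescently
    labeled insulin into a kinetic and thermodynamic description of hexamer
    assembly. Implements EMCCD photon calibration from a Poisson-Erlang pixel
    noise model, illumination-profile correction, sub-pixel particle
    localization and ROI photometry, idealization of single-particle photon
    traces with a frozen seven-state Gaussian hidden Markov model, dwell-time
    maximum-likelihood rate estimation with transition-density (CHESS)
    accounting, solution-composition estimation from assembly step sizes,
    transition-state-theory free energies, and mass-action simulation of
    oligomer populations with Hill-equation apparent affinities. A synthetic
    data module generates ground-truth state paths, photon traces and full
    camera-realistic movies so that every stage is testable by parameter
    recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    deSolve,
    minpack.lm,
    jsonlite,
    tiff,
    nortest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
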