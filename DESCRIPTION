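Package: edeform
Title: Viscoelastic Modelling of Red Blood Cell Electrodeformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and inverse fitting of red blood cell
    electrodeformation under amplitude-modulated dielectrophoresis (DEP).
    Implements the single-shell ellipsoid dielectric model (complex
    permittivities, depolarization factors, Clausius-Mossotti factor), an
    effective-dipole-moment DEP force with a finite-difference field solver
    for interdigitated electrode arrays, amplitude-shift-keying loading
    envelopes, a nonlinear Kelvin-Voigt model of membrane shear deformation,
    recovery-time and material-law fitting from cell-track time series,
    stress-strain hysteresis energy, and a synthetic-track generator for
    end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
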