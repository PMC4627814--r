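Package: endomech
Title: Membrane Mechanics of Endocytosis Under Turgor Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the plasma-membrane invagination formed during
    endocytosis in walled (turgid) cells as a pressurized elastic Helfrich
    surface pulled by an apical point force.  Solves the axisymmetric shape
    equations as a free-boundary value problem, traces force-length curves by
    pseudo-arclength continuation with fold detection, classifies
    spontaneous-curvature-driven shape instabilities (smooth, hysteresis and
    no-equilibrium regimes), supports anisotropic BAR-domain curvature and
    heterogeneous rigidity, and fits model parameters to traced membrane
    contours.  Includes an independent direct energy-minimization oracle and
    a synthetic pseudo-tomography contour generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
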