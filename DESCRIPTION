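Package: microrheo
Title: Computational Passive-Probe Microrheology of Biomolecular Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for computational passive-probe microrheology of
    coarse-grained protein condensate simulations. Converts probe-particle
    trajectories into frequency-dependent elastic and viscous moduli via an
    analytic power-law (BSW-like) parametrization of the mean-square
    displacement and the inertial generalized Stokes-Einstein relation, with an
    independent Green-Kubo route from pressure-tensor time series, probe-design
    diagnostics (FCC rough-sphere builder, hydrodynamic radius from the
    probe-residue RDF, no-slip velocity profiles, correlation-length and
    interaction-strength criteria), hydropathy-scale force-field utilities, and
    an exact generalized-Langevin fixture generator that provides analytic
    ground truth for the full analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
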