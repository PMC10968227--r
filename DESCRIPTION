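Package: aneufsi
Title: Fluid-Structure Interaction Modelling of Sidewall Aneurysm Haemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitioned fluid-structure interaction (FSI) framework for
    intracranial-aneurysm haemodynamics on an idealized sidewall geometry: a
    spherical bulge on a toroidal parent vessel. Provides parametric geometry
    construction and structured tetrahedral meshing with boundary-layer
    grading, a stabilized (variational-multiscale type) P1-P1 finite-element
    solver for the incompressible Navier-Stokes equations in an arbitrary
    Lagrangian-Eulerian frame with BDF2 time stepping, a mixed
    displacement-pressure solver for a neo-Hookean/Simo-Taylor hyperelastic
    arterial wall, Dirichlet-to-Neumann coupling accelerated by Aitken
    dynamic relaxation, and post-processing of the standard haemodynamic
    indicators (wall shear stress, TAWSS, OSI, intrasaccular swirl rate,
    aneurysm volume variation). Includes pulsatile-waveform calibration,
    resistance outlet boundary conditions, analytic verification fixtures
    (Poiseuille, Womersley, shell inflation, pressure-wave propagation) and a
    configuration-driven pipeline comparing rigid and compliant wall
    modelling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
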