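Package: cardioem
Title: Orthotropic Electro-Viscoelastic Cardiac Electromechanics with
    Stress-Assisted Diffusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coupled cardiac electromechanics on simplicial meshes: the
    four-variable minimal human ventricular action-potential model, monodomain
    propagation with stress-assisted and deformation-dependent conductivity,
    incompressible orthotropic Holzapfel-Ogden mechanics with active stress or
    active strain coupling and Kelvin-Voigt viscosity, discretised with a
    stabilised three-field (Kirchhoff stress, displacement, pressure)
    mixed-primal finite element scheme. Includes manufactured-solution
    convergence drivers, S1-S2 reentry protocols, conduction-velocity studies
    and the Cook membrane and cantilever beam mechanics benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
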