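Package: hemolbm
Title: Immersed-Boundary Lattice Boltzmann Simulation of Red Blood Cells
    and Drug Carriers in Microvessel Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A coupled immersed-boundary / lattice Boltzmann (IB-LBM) solver
    for cell-scale hemodynamics. Blood plasma is modelled with a D3Q19
    single-relaxation-time (LBGK) lattice Boltzmann scheme with Guo forcing
    and halfway bounce-back walls; red blood cells and micrometric drug
    carriers are closed triangulated membranes carrying Skalak in-plane
    elasticity, dihedral-angle bending, and global area/volume constraints,
    coupled to the fluid through a two-point immersed-boundary kernel.
    Includes biconcave and spherical mesh generators, physical/lattice unit
    conversion, straight and curved microvessel geometries, Poiseuille and
    sheared-capsule validation cases, and migration diagnostics (radial
    distance, Taylor deformation parameter, equilibration time).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
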