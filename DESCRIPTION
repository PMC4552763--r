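Package: hemoflow
Title: Particle-Based Blood Flow with Open Inflow/Outflow Boundary Conditions
Version: 1.0.0
Authors@R:
    person("hemoflow", "developers", email = "hemoflow@example.org", role = c("aut", "cre"))
Description: Dissipative particle dynamics (DPD) simulation of plasma and
    coarse-grained red blood cells (triangulated membranes with worm-like-chain
    elasticity, bending resistance, membrane viscosity and area/volume
    constraints) in microvessels. Implements open (non-periodic) boundary
    conditions for multiphase particle suspensions: a periodic generating
    region acts as an inflow source via copy-border duplication of particles
    and whole cells (with slaved motion until release), and an adaptive
    probabilistic reflecting membrane controls the outflow density. Ships
    frozen-particle wall geometries (straight tubes, Y-bifurcations, imported
    point-cloud networks), Poiseuille-flow validation utilities, and
    plasma-skimming scenarios measuring red-blood-cell recovery efficiency at
    microvascular bifurcations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
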