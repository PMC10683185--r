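Package: nanosolv
Title: Metropolis Monte Carlo Solvation and Free-Energy Perturbation for
    Nanotube Drug Carriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rigid-solute Metropolis Monte Carlo simulation in explicit
    three-site water with Lennard-Jones plus Coulomb energetics, aimed at
    solvation of drug-nanotube systems such as sulfasalazine on a
    boron-nitride nanotube. Includes a synthetic structure generator
    (hydrogen-capped zigzag BN nanotubes, an idealized sulfasalazine
    fixture, complex placement, water-box solvation), free-energy
    perturbation by staged solute annihilation (Zwanzig estimator,
    soft-core coupling), a thermodynamic cycle for association free
    energies, cylindrical radial distribution functions for hydration
    structure, and a bookkeeping layer for quantum-mechanical binding
    energies and AIM bond-critical-point descriptors checked against
    shipped reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
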