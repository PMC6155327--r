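Package: sgdml
Title: Symmetrized Gradient-Domain Machine Learning Force Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Data-driven construction of molecular force fields by
    gradient-domain kernel ridge regression with automatic discovery of
    permutational symmetries (sGDML). Recovers physically relevant atom
    relabelings from a set of molecular conformations via pairwise
    eigenvector-based graph matching and minimum-spanning-tree
    synchronization, trains a symmetrized force-field kernel in closed form
    on reference forces, predicts energies and forces for new geometries,
    and runs classical molecular dynamics with the trained model to extract
    observables such as dihedral-angle distributions, conformer occupations
    and vibrational spectra from velocity autocorrelation functions.
    Includes extended-XYZ dataset input/output, energy-distribution
    preserving subsampling, and synthetic molecular systems with analytic
    toy potentials for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    clue,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
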