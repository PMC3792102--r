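Package: tsadesign
Title: Transition-State-Analogue-Guided Enzyme Redesign
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational enzyme redesign driven by transition state
    analogues. Evaluates enzyme-ligand interaction energies under a
    molecular-mechanics potential with generalized-Born implicit solvation,
    accessible-surface-area nonpolar solvation and flat-bottom NOE catalytic
    restraints; runs stochastic redesign trajectories (backbone perturbation,
    rotamer assignment, energy relaxation, Metropolis simulated annealing)
    that minimize substrate- or analogue-based objectives under
    alignment-derived sequence constraints; correlates interaction energies
    with Michaelis-Menten parameters through effective-temperature linear
    models; and analyzes the amino-acid composition of the resulting mutant
    libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
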