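Package: oxpot
Title: One-Electron Oxidation Potentials of Solvated Molecules from
    Static and Dynamic Protocols
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts quantum-chemical energies of neutral and cationic
    solvated molecules into one-electron oxidation potentials referenced
    to the standard hydrogen electrode. Implements the static direct
    protocol and two thermodynamic cycles, ensemble-based dynamic
    protocols (direct potential-energy averages and the Marcus
    linear-response half-sum of vertical ionization and attachment
    energy gaps), diagnostics for the validity of the linear-response
    regime with a quadratic-coupling correction for nonlinear solvation,
    Boltzmann tautomer weighting of potentials, convergence analysis
    with respect to the number of sampled snapshots, and benchmarking of
    computed potentials against experimental ranges. A synthetic
    ensemble generator with known ground truth supports validation of
    every stage without electronic-structure or molecular-dynamics
    calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    nortest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
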