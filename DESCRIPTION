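Package: dooit
Title: Dual-Objective nuSVR Model Selection for Solubility in Binary Solvent Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building quantitative structure-property (QSPR) models of
    drug solubility in binary solvent mixtures from COSMO-RS derived descriptors.
    Implements descriptor construction (interaction-energy, chemical-potential and
    condensed sigma-potential features for solutes and mole-fraction-weighted solvent
    mixtures), thermodynamic curation models for literature solubility tables
    (Buchowski-Ksiazczak lambda-h, three-parameter van't Hoff, Jouyban-Acree), and a
    dual-objective nu-support-vector-regression model-selection pipeline (DOO-IT):
    Pareto-front extraction over cross-validated accuracy and support-vector ratio,
    one-standard-error candidate selection, permutation-importance backward feature
    pruning, and multi-run stability analysis with composite-score champion selection.
    Includes seeded synthetic-data generators so the full pipeline is testable without
    external data, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
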