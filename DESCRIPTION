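Package: AlertAD
Title: Structural Alert Screening and Dose Co-Factoring for Drug-Induced
    Autoimmune Disease Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens drug structures (SMILES) against a library of reactive
    metabolite structural alerts (SMARTS), builds 2x2 contingency association
    statistics between alert flags and drug-induced autoimmune disease labels
    with daily-dose co-factoring (cutoff 100 mg/day), trains and validates a
    gradient-boosted tree risk classifier with permutation-null testing and
    additive feature attributions, computes conceptual-DFT reactivity
    descriptors (hardness, chemical potential, electrophilicity index) from
    frontier orbital energies, and generates synthetic drug sets with planted
    alert odds ratios for end-to-end testing. Substructure chemistry is
    delegated to RDKit through the system 'python' interpreter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: python (>= 3.8) with rdkit on PATH
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
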