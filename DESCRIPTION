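Package: borysite
Title: Site-Level Prediction of Iridium-Catalyzed C-H Borylation Regioselectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting which aromatic C-H positions of a substrate
    undergo iridium-catalyzed borylation. Curates raw reaction SMILES into a
    clean borylation dataset by fragmenting products along C-B bonds and
    matching fragments back to substrates, enumerates the symmetry-distinct
    candidate monoborylation sites of a molecule, featurizes each candidate
    site reaction with a differential reaction fingerprint (the hashed
    symmetric set difference of circular-substructure shingles of reactants
    and products), and trains random-forest site-reactivity classifiers and
    site-yield regressors on top. Includes site- and molecule-level evaluation
    metrics (MCC, PPV, all-sites accuracy, major-product accuracy),
    chemistry-aware dataset splits, and a seeded synthetic reaction generator
    whose regioselectivity follows published steric and electronic
    borylation guidelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    generics,
    dplyr,
    ggplot2,
    igraph,
    ranger,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
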