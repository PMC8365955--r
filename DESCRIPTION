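Package: hergstack
Title: Step-Wise Stacked Deep Learning for hERG Channel Blocker Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies small molecules as hERG potassium-channel blockers or
    non-blockers from SMILES input using a step-wise-trained meta-ensemble of
    five neural base models, each consuming a different molecular view
    (physicochemical descriptor panel, molecular graph, combined substructure
    fingerprints, SMILES token embeddings and fingerprint-index embeddings).
    Includes the surrounding machinery: SMILES standardization and label
    reconciliation, four-way step-wise data splitting and consecutive-splitting
    cross-validation, a base-feature combination search over all 31 subsets,
    a binary-classification metric suite (sensitivity, specificity, predictive
    values, accuracy, balanced accuracy, Matthews correlation, ROC AUC),
    Tanimoto chemical-diversity analysis with t-SNE projection, and a seeded
    synthetic SMILES generator with a planted structure-activity rule for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
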