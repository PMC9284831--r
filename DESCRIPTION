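Package: chemclust
Title: Network-Derived Functional Clustering and Structure-Based
    Classification of Chemicals
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives biological distances between chemicals from scored
    chemical-protein and protein-protein interaction networks, clusters
    chemicals into functional groups by hierarchical clustering with
    support filtering, and trains structure-based classifiers (Morgan
    fingerprint, per-character feature matrix, and token-sequence models
    over SMILES, including a pretrained language-model route) that assign
    novel compounds to those clusters.  Includes SMILES parsing,
    canonicalization and enumeration-based augmentation, pair-encoding
    tokenization, cluster protein annotation at two confidence cutoffs,
    cross-validated F1 evaluation and fold-wise randomization tests, and
    synthetic fixture generators for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
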