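Package: bitterrec
Title: Hybrid Recommendation of Bitter Taste Receptor Targets for Small
    Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which bitter taste receptors (TAS2Rs) a bitter
    molecule activates, treating the task as a hybrid recommendation
    problem on a sparse ternary ligand-by-receptor association matrix.
    Combines chemical descriptors of ligands and receptors with
    neighbor-informed features that weight known positive and negative
    associations by ligand-to-ligand similarity (fingerprint Tanimoto,
    collaborative) and receptor-to-receptor similarity (collaborative,
    sequence identity and BLOSUM62-based similarity over a multiple
    sequence alignment and its binding-site columns). Includes a
    gradient-boosted decision tree classifier with native missing-value
    handling, leakage-safe repeated train/test splitting for the
    filling-the-gaps and new-ligands (cold start) scenarios, baselines,
    precision-recall evaluation with confidence intervals and prediction
    bands, association-matrix completion, cross-species functional
    analog analysis, batch prediction, and a synthetic data generator
    with planted block structure for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    matrixStats,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
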