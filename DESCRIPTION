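Package: mhcforest
Title: Random-Forest Prediction of MHC Class I Peptide Presentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains per-allele random-forest classifiers that distinguish
    MHC class I-presented 9-mer peptides from proteome-derived decoy
    nonamers. Peptides are encoded with configurable biophysical and
    sequence features (hydropathy, aromaticity, charge, residue mass,
    one-hot and BLOSUM62 encodings); models are evaluated with the
    decoy-excess protocol (precision in the top 1% of a 1:99
    binder:decoy mixture, area under the precision-recall curve, AUROC),
    feature subsets are searched exhaustively, and Gini-impurity
    importances are aggregated by peptide position. Includes downstream
    analyses (score-affinity rank correlation, Cliff's delta for gene
    expression of presented genes) and a motif-based simulator so the
    whole pipeline runs on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
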