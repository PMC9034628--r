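Package: cmsnet
Title: Consensus Molecular Subtype Classification of Colorectal Cancer
    Expression Profiles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies colorectal-cancer gene-expression profiles into the
    four consensus molecular subtypes (CMS1-CMS4). Subtype-specific genes
    are selected by pairwise differential expression (log2 fold-change,
    Welch t test, Benjamini-Hochberg Q values) across the six subtype
    pairs, and a compact feed-forward neural network (two ReLU
    representation layers with dropout and L1/L2 regularisation, softmax
    output) is trained with an explicitly implemented backward pass and
    Adam optimiser. Includes macro-averaged evaluation metrics, stratified
    cross-validation, a regularisation-coefficient scan, distance
    correlation between cohorts, weight-based gene interpretability, and a
    synthetic four-class expression simulator with planted
    subtype-specific genes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
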