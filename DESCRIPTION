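Package: trgtools
Title: Classification and Comparative Analysis of Taxonomically Restricted Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying taxonomically restricted genes (TRGs):
    classification of genes as lineage-restricted or shared from BLAST-style
    homology hit tables with domain-based exclusion, relaxed-cutoff
    sensitivity scans and per-genome best-hit profiles; Fisher
    Z-transformed coexpression features against pathway gene sets;
    elastic-net logistic regression with cross-validated ROC AUC to
    predict gene essentiality from coexpression; flanking-gene expression
    and chromatin-signal window analyses; Markov Clustering of
    protein-protein interaction networks with hypergeometric enrichment;
    and class-wise comparisons of protein disorder, coiled-coil content
    and dN/dS by functional class.  A synthetic-data generator emulates
    every input with configurable planted effects so the whole pipeline
    is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    glmnet,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
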