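Package: exprphylo
Title: Phylogenetic Comparative Analysis of Tissue-Biased Gene Expression
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for comparative transcriptomics across a species
    phylogeny: cross-species TPM10k normalization and homology-group
    averaging of per-library transcript abundances, negative-binomial
    differential expression between tissues with core tissue-specific
    cohort calling, linear-model partitioning of expression variance into
    tissue, species and residual components over nested clades,
    Brownian-motion ancestral state reconstruction of log expression-bias
    ratios with per-branch scaled evolutionary changes and qualitative
    shift calling, and gene-by-gene evolutionary correlation networks
    compared against known interaction annotations. A synthetic-data
    generator produces expression tables, trees, homology maps and
    interaction labels with the statistical structure the analysis
    assumes, together with ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
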