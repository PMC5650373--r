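Package: pairedCoex
Title: Paired Tumor/Normal Differential Expression and Signed
    Co-Expression Network Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-quantification analysis of paired tumor/normal bulk
    RNA-seq FPKM matrices: abundance filtering, per-gene paired ANOVA
    with Benjamini-Hochberg false discovery rate control and linear
    fold-change calling, unsupervised hierarchical clustering and
    principal component analysis with histology-versus-cluster
    discordance reporting, self-contained hypergeometric gene-set
    enrichment, signed Pearson correlation ("relevance") network
    construction at a fixed coefficient threshold, degree-based hub
    gene ranking with neighborhood extraction, and eigengene-based
    inter-module correlation classification. Includes a synthetic
    paired-cohort generator with planted differential expression,
    correlated latent-factor modules and planted hub genes, so that
    every stage of the cascade is verifiable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    Network, Clustering, PrincipalComponent
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
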