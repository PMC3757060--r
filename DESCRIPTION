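Package: coregFFL
Title: MicroRNA and Transcription Factor Co-Regulatory Feed-Forward Loop
    Network Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for discovering microRNA and
    transcription factor (TF) co-regulatory feed-forward loops (FFLs) from
    two-group expression experiments. Starting from log2 expression matrices
    of microRNAs and mRNAs for samples split into two phenotype groups (for
    example high versus low proliferation), the package computes moderated
    two-sample statistics with empirical-Bayes variance shrinkage, assigns
    inversely regulated high-efficacy target genes to differentially
    expressed microRNAs, keeps microRNAs whose targets are enriched among
    differentially expressed genes (hypergeometric test with a permutation
    enrichment-score calibration), clusters target genes by Gene Ontology
    semantic similarity (Resnik information content, FANNY fuzzy clustering
    with Dunn coefficient and Dunn index model selection), tests 3-node and
    4-node FFL motifs with pair-specific hypergeometric nulls, and merges
    significant motifs into typed co-regulatory networks with centralities,
    hub calling, random-walk community detection and per-module gene-set
    annotation. A synthetic-data generator with planted ground truth
    supports calibration and recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    cluster,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'coregFFL-package.R'
    'diffexpr.R'
    'enrich.R'
    'fanny.R'
    'gosim.R'
    'io.R'
    'motifs.R'
    'network.R'
    'pipeline.R'
    'simulate.R'
    'targets.R'
    'utils.R'
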