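Package: statenet
Title: Kinship-Aware Co-Expression and Co-Accessibility Networks for
    Pluripotent Cell States
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers genome-wide gene co-expression and regulatory
    co-accessibility networks across cohorts of related donors. Pairwise
    feature associations are tested with a linear mixed model that uses a
    kinship matrix as the random-effect covariance (spectral-decomposition
    fast path with a generalized-least-squares oracle), significant positive
    associations are assembled into a network, and modules are detected with
    the Leiden algorithm under a parameter sweep with a permutation null.
    Includes module scoring from intramodular Pareto members, two-state
    cell-state deconvolution from signature matrices, interval-level
    annotation of ATAC-seq peaks (target genes, collapsed chromatin states,
    reciprocal overlap, score-quantile reference peak selection,
    transcription-factor group collapsing), exact 2x2 enrichment testing,
    allele-specific chromatin accessibility testing, and a synthetic cohort
    generator that emulates the assumed data structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    edgeR,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: GeneExpression, ATACSeq, NetworkInference, Epigenetics
RoxygenNote: 7.3.3
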