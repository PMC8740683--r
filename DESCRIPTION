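Package: ReVarNet
Title: Regulatory-Network Interpretation of Noncoding and Coding Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative genetic analysis of case-control whole-genome
    cohorts through cell-type-specific regulatory networks. Builds
    regulatory-element to target-gene networks from chromatin-loop calls
    (HiChIP-style BEDPE) and ATAC-seq peaks, tests network enrichment of
    GWAS summary statistics under a spike-and-slab effect-size prior fitted
    by variational inference and summarized as Bayes factors, detects
    regulatory elements with differential predicted chromatin openness
    between cases and controls from personal genomes, scores per-gene
    burden of rare nonsynonymous variants, and combines coding and
    noncoding evidence at the gene-set level with Fisher's method. Seeded
    synthetic-data generators with planted ground truth make the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    fgsea,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
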