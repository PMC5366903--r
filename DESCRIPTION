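Package: cnvburden
Title: Multi-Caller Consensus CNV Calling, CNV-Region Clustering and
    Burden Analysis for Placental and Parental Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds per-sample consensus copy-number variants (CNVs) from
    parallel calls of several detection algorithms under a reciprocal-overlap
    criterion, clusters consensus CNVs across samples into CNV regions
    (CNVRs), annotates pericentromeric and subtelomeric genomic context,
    computes per-sample burden summaries and case-control group statistics
    (Shapiro-Wilk gated Welch/Wilcoxon comparisons, Fisher's exact sharing
    tests, large-CNV profiles), and links CNVRs to gene expression through
    FPKM median comparisons and z-score carrier analyses on
    median-of-ratios normalized counts. Includes a fully seeded synthetic
    cohort generator (group-structured true CNVs, imperfect callers with
    breakpoint jitter and false positives, negative-binomial expression
    with dosage effects) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    DESeq2
Config/testthat/edition: 3
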