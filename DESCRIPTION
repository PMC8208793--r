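Package: subtelomeR
Title: Positional Enrichment of Age-Related Expression Changes Near Telomeres
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the telomere position effect in bulk RNA-seq
    cohorts: identifies age-related differentially expressed genes from raw
    count matrices (TMM normalization, per-gene linear models with an age
    covariate, Bonferroni correction), bins genes by distance to chromosome
    ends, computes the per-bin odds ratio of up- versus downregulated genes
    with Fisher exact tests and Woolf confidence intervals, runs the matching
    centromere control, compares gene-age correlations and protein-protein
    interaction subnetwork degrees between gene groups, and classifies Hi-C
    chromatin loops by anchor distance to chromosome ends. A synthetic-data
    module generates annotations, count matrices with planted subtelomeric
    up-bias, loop sets and scored interaction networks with known ground
    truth, so the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    edgeR,
    igraph,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
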