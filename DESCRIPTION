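Package: methdriver
Title: Methylation-Driven Path Analysis over Signed Protein Interaction
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of differential DNA methylation, differential
    expression, copy number and protein-protein interaction data in paired
    tumor/normal cancer cohorts. Collapses per-CpG methylation changes to one
    representative change per gene, estimates a Cauchy location/scale model of
    pooled methylation changes to derive a data-driven "large methylation
    change" threshold (center plus two scale parameters), and searches a
    high-confidence signed (activation/inhibition) interaction network with a
    breadth-first, sign-consistency-constrained traversal for shortest
    methylation-driven paths linking large methylation changes to dysregulated
    cancer driver genes. Includes distance summaries, cross-cohort sharing
    tables, an empirical randomization null, a segmental-mean copy-number
    confounder filter, and a fully synthetic data generator with ground-truth
    manifests for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    igraph,
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
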