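Package: viroscape
Title: Spatial Ecology and Gene-Sharing Network Enrichment for Soil Viromes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for spatially explicit analyses of soil viral communities
    profiled by viral-size-fraction metagenomics. Implements filtering and
    normalization of vOTU coverage tables, Bray-Curtis beta-diversity with
    principal coordinates analysis and PERMANOVA, distance-decay statistics
    with same-timepoint pair masking, within-population microdiversity via
    sample-specific consensus sequences and pairwise consensus ANI, two-group
    indicator-species (IndVal) permutation tests, and a local-neighborhood
    hypergeometric trait-enrichment scan on viral gene-sharing networks with
    Holm family-wise error control. A synthetic-data generator produces full
    input bundles with planted spatial decay, treatment effects, genotype
    divergence, and an enriched network module for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    vegan,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
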