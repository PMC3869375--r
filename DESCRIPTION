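Package: enhancerIslands
Title: Island-Based ChIP-Seq Enrichment Calling and Enhancer Chromatin-State Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying how a histone H3K4
    mono-/di-methyltransferase (MLL4/KMT2D) marks cell-type-specific
    enhancers. Implements SICER-style island calling of ChIP-enriched
    regions against control libraries with a knockout-based antibody
    specificity filter, four-class chromatin-state classification of
    enhancers and promoters from H3K4me1/H3K4me3/H3K27ac islands,
    transcription-factor co-localization and log-space enrichment
    statistics (hypergeometric, binomial, Poisson), RPKM-based expression
    regulation and knockout-dependence calls, nearest-TSS enhancer-to-gene
    assignment with category resolution, and a recovery analysis for
    ectopic C/EBPbeta-induced enhancers. Ships a seeded synthetic-data
    generator that emulates the tag-library and expression structure the
    pipeline assumes, with ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
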