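Package: statepipe
Title: Interactome Scoring and Chromatin-State Integration for Naive and
    Primed Pluripotency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two linked analyses of naive versus primed human
    embryonic stem cells: (1) calling bait-specific protein interactors
    from replicated AP-MS spectral-count tables using a modified
    enrichment statistic, per-experiment empirical p-values, a combined
    cumulative probability score and an FDR cutoff, with CRAPome-style
    contaminant filtering; and (2) integrating chromatin-remodeler and
    histone-mark peak sets into merged occupancy matrices, k-means
    chromatin-state clusters with rule-based enhancer/promoter
    annotation, nearest-TSS target assignment, and differential
    expression/accessibility statistics. Includes synthetic-data
    generators that emulate the statistical structure of such studies so
    every pipeline stage carries a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    tidyr,
    rlang,
    GenomicRanges,
    IRanges,
    S4Vectors,
    limma
Suggests:
    testthat (>= 3.0.0),
    mclust,
    rtracklayer,
    withr,
    jsonlite
Config/testthat/edition: 3
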