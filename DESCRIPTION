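Package: methimprint
Title: Discovery of Tumor-Specific DNA Demethylation Imprints in Inactive Chromatin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying CpGs with tumor-specific DNA
    demethylation located in chromatin-inactive regions, using conventional
    mantle cell lymphoma (cMCL) versus normal B-cell references as the model
    system. Implements threshold-based CpG selection with
    proliferation-drift filtering, hierarchical ChromHMM chromatin-state
    classification, Monte-Carlo permutation enrichment statistics,
    clustering-based NBC-het/NBC-hom subclassification, position weight
    matrix motif enrichment against a lognormal tile background, TF
    peak-overlap enrichment, CpG-to-gene assignment with expression-category
    enrichment, and a synthetic-data generator with planted ground truth so
    every stage is testable without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    cluster,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
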