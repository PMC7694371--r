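Package: concordia
Title: Rank-Based Integration of Transcriptomic and Proteomic
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates paired differential-expression results from a
    transcriptomic and a proteomic study of the same two-group contrast
    using direction-specific average ranks of log2 fold changes, so that
    concordantly and discordantly regulated genes can be identified
    without assuming comparable fold-change scales across platforms.
    Includes identifier harmonisation and duplicate collapsing, a
    from-first-principles pre-ranked gene-set enrichment analysis
    (weighted running-sum enrichment score, gene-set resampling null,
    normalised enrichment score, permutation FDR) with a dual-level
    significance filter, overlap against plasma-proteome and drug-gene
    interaction reference lists, and a seeded synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fgsea,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
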