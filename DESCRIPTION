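Package: wgtsbench
Title: Benchmarking Analytics for Clinical Whole-Genome and Transcriptome
    Tumor Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to exercise and benchmark the bespoke analytics behind an
    integrated clinical cancer whole-genome plus transcriptome (cWGTS)
    workflow: ensemble somatic/germline variant consensus with panel-of-normals
    artifact filtering, cancer-cell-fraction computation and clone clustering,
    cross-assay concordance with an intratumor-heterogeneity proportion test,
    sequencing-depth sensitivity curves with an analytic binomial
    detection-power model, coding tumor mutational burden, microsatellite
    instability scoring, mutational-signature refitting by non-negative least
    squares, and rule-based integrative variant prioritization. A bundled
    simulator generates fully specified synthetic tumors (clone trees, copy
    number, assay read counts, caller outputs, expression, cell-free DNA) so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
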