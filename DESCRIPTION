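Package: mirskin
Title: Small RNA-Seq miRNA Profiling and Novel miRNA Prediction for
    Two-Condition Skin Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained re-implementation of a classic two-library
    small RNA sequencing workflow for miRNA discovery in skin: adapter
    trimming and length filtering of raw reads, collapsing into unique
    sequence tags, hierarchical (priority-rule) annotation against
    non-coding RNA, repeat, exon and intron reference sets, conserved
    miRNA identification against a mature catalog with isomiR end
    heterogeneity and arm-usage analysis, reads-per-million normalized
    differential expression with the Audic-Claverie count test, rule-based
    novel miRNA prediction from genomic hairpins filtered on minimum free
    energy and the minimal folding free energy index (MFEI), rule-based
    miRNA target-site scanning, and Livak delta-delta-CT qPCR
    quantification. Ships a seed-deterministic synthetic-data generator
    (planted hairpin loci, planted fold changes, contaminant fragments)
    so the entire pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
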