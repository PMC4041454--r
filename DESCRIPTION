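Package: cistromix
Title: Integrative Cistrome, Transcriptome and Clinical-Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing transcription-factor ChIP-seq peak sets
    (BED half-open intervals, consensus peaks, pairwise overlap matrices
    and their clustering), testing peak-set and gene-set overlap
    (hypergeometric and binomial tails, Benjamini-Hochberg FDR, a seeded
    length-preserving genomic permutation null), relating peaks to genes
    (windowed TSS assignment, closest feature, distance profiles),
    deriving concordant differentially expressed core gene sets from
    overexpression/knockdown contrasts, integrating binding with
    expression (fraction-bound summaries, gene-panel regulation checks),
    and clinical survival statistics (H-scores, median-unbiased
    quantiles, Kaplan-Meier with Greenwood log-log intervals, log-rank,
    maximally selected cutpoints, Cox proportional hazards with Efron
    ties). A seeded synthetic-data module generates every input class
    with planted, recoverable structure so the full pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
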