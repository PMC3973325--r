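Package: gantcscope
Title: GANTC Methylome, Motif Distribution and Methylation-Coupled
    Expression Analysis for Alphaproteobacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying cell cycle-regulated N6-adenine methylation
    of GANTC motifs by the orphan methyltransferase CcrM in Caulobacter and
    related Alphaproteobacteria. Implements genome-wide motif counting with
    observed/expected statistics under a single-base composition null,
    per-strand methylated-population fraction estimation from SMRT
    inter-pulse-duration (IPD) ratios via a two-state linear mixing
    calibration, classification of under-methylated and asymmetrically
    methylated sites, smoothed chromosomal methylation profiles, promoter
    motif extraction and cross-species conservation scoring, and Fisher
    exact gene-set enrichment linking methylation to differential
    expression. A synthetic-data generator produces genomes, kinetics and
    expression data with planted structure so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
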