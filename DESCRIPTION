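Package: scContacts
Title: Single-Cell 3D Genome Contact Analysis with Compartment Scoring,
    Stage Typing and Pooled-Sample Demultiplexing
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of per-cell chromatin contact lists from single-cell
    whole-genome chromosome-conformation (Dip-C style) experiments.
    Computes single-cell A/B compartment (scA/B) scores per megabase bin
    against a reference compartment track, embeds and clusters cells into
    age-ordered structure stages, quantifies ultra-long-range (>= 10 Mb)
    intra-chromosomal contact fractions and inter-chromosomal hub
    enrichment, identifies dynamic compartment regions across stages, and
    demultiplexes pooled cells to donors by SNP genotype likelihood and to
    sex by X/autosome coverage ratio. Includes a calibrated synthetic
    single-cell contact generator with full ground truth so every stage of
    the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
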