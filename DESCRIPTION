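Package: epiDRS
Title: Epitranscriptomic Profiling of Bacterial Stress Responses from
    Nanopore Direct RNA Sequencing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection and characterization of RNA modifications from
    nanopore direct RNA sequencing (DRS) basecalling errors. Computes
    per-position basecalling-error proportions (BCError) from alignments,
    derives differential error profiles against unmodified in vitro
    transcribed (IVT) controls, calibrates classification thresholds by
    precision and recall against known ribosomal RNA modification sites,
    annotates putative modification sites by transcript region, analyses
    anticodon-loop modification changes and maturation of pre-tRNAs, and
    scores coding sequences for wobble-modification-dependent codon
    abundance. Includes a synthetic-data generator that emulates
    modification-dependent basecalling error so every analysis stage can
    be exercised and validated without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    BiocGenerics,
    graphics,
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
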