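Package: sineScout
Title: SINE Insertion Ascertainment, Cross-Genome Genotyping and Repeat
    Landscape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of short interspersed element
    (SINE) insertions across a clade of genome assemblies. Ascertains
    full-length elements from RepeatMasker-style annotation tables, extracts
    flanked locus sequences, genotypes insertion presence/absence in other
    genomes by seeded local alignment and gap detection, classifies loci
    into specificity categories (fixed-present, lineage-specific,
    polymorphic, missing-value) with clade sub-categories and incomplete
    lineage sorting flags, quantifies the surrounding repeat landscape
    (proximity, genome content, divergence histograms, nested intra-repeat
    integration), detects target-primed reverse transcription hallmarks
    (target-site duplications, poly-A tails, endonuclease cleavage motifs),
    discovers young subfamilies from lineage-specific copies via
    co-segregating diagnostic substitutions, and builds neighbor-joining
    trees with bootstrap support. A clade simulator with planted insertions
    provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
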