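Package: ridgescan
Title: Transcriptome Maps, RIDGE Calling and Syntenic Breakpoint Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds running-median transcriptome maps from per-gene expression
    ordered along chromosomes, calls regions of increased (RIDGE) and decreased
    (anti-RIDGE) gene expression by thresholding against the genomic median,
    tests region counts against a gene-order permutation null, relates the maps
    to genomic feature tracks (gene density, GC content, gene and intron
    length, minimal-intron density), and quantifies enrichment of evolutionary
    breakpoints from synteny blocks within and between two genomes' regions.
    Includes a synthetic-data generator with planted expression domains so the
    whole pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
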