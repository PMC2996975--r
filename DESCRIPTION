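Package: mitotrna
Title: Translational and Deamination Constraints on Vertebrate
    Mitochondrial tRNA Gene Arrangement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether the positions of tRNA genes in
    vertebrate mitochondrial genomes are shaped by translational
    efficiency and by deamination avoidance. Reads annotated circular
    mitochondrial genome records (GenBank flat files), counts codon
    usage over the 13 protein-coding genes under the vertebrate
    mitochondrial genetic code, measures strand-aware base-pair
    distances from the control region to each tRNA gene, and relates
    usage to position with exact Mann-Whitney tests, phylogenetically
    independent contrasts (through-origin correlation), and a
    Fisher/Stouffer meta-analysis across tRNA families. A second
    analysis computes single-strand exposure durations under the
    strand-displacement model of mtDNA replication and correlates them
    with anticodon G+T content. A seeded synthetic-data generator
    produces annotated circular genomes, trees and tip data with known
    ground truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
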