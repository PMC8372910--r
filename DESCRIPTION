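Package: plastomeHotspots
Title: Plastome Variability Hotspots and DNA Barcode Utility Scoring
Version: 0.1.0
Authors@R:
    person("Plastome", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of annotated plastid genomes: extraction of
    shared protein-coding genes, rRNAs and intergenic spacers; sliding-window
    nucleotide diversity and parsimony-informative-site statistics; Kimura
    2-parameter distance matrices; neighbor-joining trees, monophyly and
    backbone-topology tests; a six-point phylogenetic utility score for ranking
    candidate barcode regions; parsimony mapping of gene loss and
    pseudogenization events; inverted-repeat boundary detection; and a
    plastome-set simulator with known truth for closed-loop testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
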