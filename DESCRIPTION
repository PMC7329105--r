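Package: aphidiet
Title: Aphid Prey Detection in Ladybird Guts by COI Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-throughput-sequencing diet analysis of aphidophagous
    predators. Covers in-silico evaluation of degenerate COI primers
    (physical properties and position-weighted mismatch-penalty amplification
    prediction), assessment of the taxonomic resolution of a short COI
    amplicon against a labelled barcode library, a reads-to-diet metabarcoding
    pipeline (quality trimming, pair merging, tag demultiplexing,
    abundance and chimera filtering, centroid clustering, identity-threshold
    taxonomic assignment, tag-jump mitigation), and downstream composition
    statistics (recovery rates, Hellinger-transformed Euclidean distances,
    stratified-permutation PERMANOVA, multivariate dispersion, NMDS).
    Includes seed-deterministic simulators for reference libraries and
    tagged paired-end gut-content read sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    S4Vectors,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
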