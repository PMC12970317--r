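Package: barcodelim
Title: Integrative Single-Locus Species Delimitation from DNA Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for delimiting putative species from a single-locus
    barcode alignment (typically mitochondrial COI). Computes Kimura
    two-parameter pairwise distances, builds a neighbor-joining guide tree,
    partitions specimens into operational taxonomic units with two
    independent delimiters (a barcode-gap threshold sweep and a Poisson
    tree processes model with maximum-likelihood and Bayesian MCMC modes),
    and reconciles the two partitions into named species hypotheses using
    congruence, divergence thresholds, a sympatry/allopatry merge rule over
    biogeographic regions, misidentification flags, and type-locality name
    assignment. A coalescent K80 sequence simulator with known species
    truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
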