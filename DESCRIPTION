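Package: irscape
Title: Genome-Wide Enrichment Analysis of Inverted Repeats
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans hard-masked genomes for windows enriched in inverted
    repeats (k-mer stems followed downstream by their reverse complement).
    Observed stem-pair counts per start-to-start distance are compared to
    expectations under an order-k Markov null model through binomial
    z-scores, summed over distance (loop-length) classes into an S
    statistic. Empirical critical values are derived from control-scenario
    genomes simulated from the fitted Markov model with the original
    ambiguity (N) mask preserved, and enriched windows are reported per
    chromosome and length class. Includes a fully seeded synthetic-genome
    generator with planted inverted repeats for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, StatisticalMethod, Coverage
RoxygenNote: 7.3.3
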