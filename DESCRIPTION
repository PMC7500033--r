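Package: mitoarc
Title: Detection and Quantification of Mitochondrial DNA Deletions from
    Split Reads on a Circular Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects deletions in circular mitochondrial genomes from
    paired-end sequencing reads using a split-read approach against a
    tandem-doubled reference, converts junction read counts into
    molecular-species frequencies and ablation levels, annotates
    deletions with terminal microhomology and repeat-tract context,
    summarises deletion patterns (binned breakpoint matrices,
    hierarchical clustering, principal components, length spectra and
    terminus histograms), and fits Monte Carlo models of
    replication-coupled deletion formation to terminus-frequency data.
    A synthetic-data generator produces circular-genome populations
    with known deletion frequencies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite,
    yaml,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
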