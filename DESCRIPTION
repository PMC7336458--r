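Package: omguide
Title: Optical-Map-Guided Long-Read Genome Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Guided overlap-layout assembly of long sequencing reads using a
    genome-wide optical map. Sequences are digested in silico with a
    restriction enzyme into ordered fragment-length maps, preliminary contigs
    are placed on the reference optical map by a block dynamic-programming
    aligner, reference fragments carry globally unique integer colors that are
    transferred to contigs and then to reads, and the colored reads guide a
    miniasm-style overlap-graph assembly in which color-inconsistent edges are
    removed so that unitigs are maximal non-branching rainbow paths. Includes
    a simulator for genomes, error-bearing reads with ground truth, and
    perturbed optical maps, plus readers and writers for FASTA, PAF, GFA, a
    plain-text optical-map format, and colored-read tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
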