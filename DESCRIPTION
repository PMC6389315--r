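Package: sbexpand
Title: Degenerative Expansion Analysis of Nonrecombining Supergenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and modelling "degenerative expansion", the
    growth in physical size of a young nonrecombining chromosome or supergene
    through the accumulation of insertions.  The package provides a synthetic
    data generator for paired haploid genomes with planted structural
    variants, dynamic-programming alignment of ordered-label (optical-style)
    maps with large-indel and overhang calling, chromosome-level enrichment
    statistics for structural variant counts and cumulative lengths, k-mer
    spectrum based genome-size and repeat-fraction estimation with paired
    comparison and propagation to supergene-scale expansion estimates,
    presence/absence indel phylogenetics across individuals, and a forward
    Wright-Fisher simulator of chromosome-length evolution under asymmetric
    insertion/deletion fitness costs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
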