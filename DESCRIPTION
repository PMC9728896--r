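Package: popgensweep
Title: Population-Genomic Diversity, Selective-Sweep, LD Decay and
    Gene-Flow Analyses with a Wright-Fisher Simulator
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Re-usable building blocks for resequencing-based population
    genomics of domesticated perennials: VCF genotype input with
    quality/missingness/frequency site filters, sliding-window nucleotide
    diversity (theta-pi, Watterson's theta-w, Tajima's D), windowed
    Weir-Cockerham FST with reduction-of-diversity (ROD) selective-sweep
    calling and gene annotation, linkage-disequilibrium decay curves with
    half-decay distance, four-population ABBA-BABA D statistics with block
    jackknife Z scores and Wright's Nm, p-distance neighbour-joining trees,
    and a seeded forward Wright-Fisher simulator (multi-deme, migration,
    bottlenecks, admixture pulses, sweep injection) providing ground truth
    for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    ape,
    stats,
    utils,
    tools,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
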