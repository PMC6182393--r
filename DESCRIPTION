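Package: lrcprofiler
Title: Paralog-Aware Annotation and Expression Analysis of Leukocyte
    Receptor Complex Ig-Like Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing expanded immunoglobulin-like receptor gene
    families of the leukocyte receptor complex (LRC). Provides functional
    classification of receptor gene models (ITIM scanning, hydropathy-based
    transmembrane prediction, charged-residue and disablement calls),
    paralog-aware RNA-seq read assignment with tiered gene/group counting
    and FPKM quantification, composite-likelihood nucleotide distances with
    minimum-evolution tree search and bootstrap support, sliding-window
    recurrence (dot-plot) comparison of assemblies with inversion and
    insertion detection, and a fully seeded synthetic-locus and read
    simulator that emulates the statistical structure of a two-clade
    receptor expansion for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    ape,
    phangorn,
    stats,
    utils,
    methods,
    tools,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
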