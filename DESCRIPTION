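Package: centrorep
Title: Pericentromeric Replication Timing and Cohesin Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how replication initiation near centromeres
    shapes sort-seq replication-timing profiles and pericentromeric cohesin
    enrichment in budding yeast. Provides a seeded synthetic-data generator
    (genomes, origin sets, Poisson sort-seq and ChIP read counts), a
    replication-kinetics model with an independent lattice fork-propagation
    oracle, a sort-seq profile pipeline (S/G2-M ratio, normalization,
    smoothing, differential tracks, peak calling), inference of per-origin
    replication delays and of the centromere-distance cutoff within which
    origin firing is delayed in a mutant, and ChIP fold-enrichment, peak and
    count-based statistics (two-dot cohesion fractions, chromosome-loss
    rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
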