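Package: barbiq
Title: Cell-Based 16S Identification and Absolute Quantification from
    Barcoded Droplet Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational core for cellularly barcoded 16S rRNA amplicon
    sequencing (the BarBIQ strategy): Poisson droplet-occupancy models,
    a droplet-sequencing simulator with ground truth, barcode and
    within-droplet 16S clustering, quality-weighted consensus calling and
    error filtering of Bar sequences, co-occurrence-based grouping of
    multi-copy 16S genes into cell-based OTUs (cOTUs), cell counting and
    absolute-abundance anchoring against an external total-abundance
    measurement (with a fragment mode for extracellular DNA), and the
    downstream statistics the method relies on: median-of-ratios size
    factors, Bray-Curtis dissimilarity, analytic rarefaction richness,
    a CV-squared technical-noise model, Poisson sampling-noise envelopes
    with a fold-change differential rule, and a PCR-error accumulation
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
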