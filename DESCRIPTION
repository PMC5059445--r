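Package: rustseq
Title: Ribo-Seq Unit Step Transformation and Codon Dwell-Time Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalization and sequence-determinant analysis for ribosome
    profiling (ribo-seq) data. Implements the Ribo-seq Unit Step
    Transformation (RUST), which converts per-codon footprint density
    profiles into binary above/below-transcript-average indicators and
    summarizes them as observed/expected metafootprint profiles with
    Kullback-Leibler divergence per position. Includes competing
    normalizations (conventional, logarithmic-mean, ribosome residence
    time), automatic A-site offset detection, a Poisson footprint
    simulator with configurable codon dwell-time grids and two noise
    models, amino-acid/dipeptide/tripeptide and peptide-property
    determinant profiling, RNA-structure window analysis, tripeptide
    synergy scoring, and prediction of footprint densities from RUST
    ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
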