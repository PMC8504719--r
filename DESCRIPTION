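Package: svrefine
Title: Single-Nucleotide Refinement of Read-Depth Structural Variant
    Breakpoints with a 1-D UNet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Read-depth based structural variant (SV) callers report deletion
    and duplication breakpoints at the resolution of their depth bins.
    'svrefine' refines such breakpoints to single-nucleotide resolution by
    segmenting base-wise read-depth windows around candidate breakpoints with
    a small one-dimensional UNet trained with a soft Dice loss.  The package
    covers the full workflow: base-wise depth extraction and background
    z-normalisation from BAM files, construction of training windows and
    per-base SV-overlap label masks from a known SV set, the UNet itself
    (built and trained in R, no external deep-learning runtime), the
    mask-to-breakpoint refinement algorithm with its 50 bp size guard, VCF
    post-processing, benchmarking metrics (Jaccard matching, precise-boundary
    summaries, distance-range change matrices, Dice and classification
    scores), and a seeded synthetic-coverage simulator that produces BAM/VCF
    fixtures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    grDevices,
    graphics,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
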