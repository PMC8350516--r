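Package: cnatrace
Title: Tracking an Emerging Tumour Subclone from Longitudinal Low-Pass
    WGS Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint analysis of longitudinal cell-free DNA copy-number
    profiles measured by low-pass whole-genome sequencing.  From
    depth-based segment copy numbers alone (no B-allele frequencies, no
    matched normal), cnatrace estimates the tumour fraction (purity) of
    each sample by matching peaks of the segment copy-number
    distribution to an integer-ploidy grid, identifies the somatic copy
    number alterations private to a single emerging subclone via a
    quasi-monotone ordering of purity-corrected copy-number changes
    against a baseline sample, and quantifies the subclone's size with a
    mean-constrained Gaussian mixture model.  A synthetic-data generator
    reproducing the statistical structure of such datasets is included
    for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
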