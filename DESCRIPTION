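Package: reprotrace
Title: Numerical Reproducibility Auditing for Neuroimaging Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies and localizes differences between executions of
    neuroimaging pipelines run on different operating systems, builds or
    clusters. Provides library-call trace difference classification
    (type-1/2/3/mismatch taxonomy), IEEE-754 single-precision forensics
    (ULP distance, flipped-bit counts, exact 30-decimal expansions),
    global and per-label Dice overlap of segmentation label volumes with
    binarized difference maps, residual rigid-transform metrics for
    motion-correction comparisons, stage-wise mean-absolute-difference
    attribution across pre-processing steps, ICA spatial component
    matching by maximal correlation with signed-part Dice, vertex-wise
    cortical-thickness difference statistics, and seeded synthetic-data
    generators with known ground truth so every comparison stage is
    testable without clinical MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    digest,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
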