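Package: rknet
Title: Unsupervised Filtering of Tumor-Level CT Slices by Embedding Clustering
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to refine radiological image stacks without manual
    screening or annotation. Raw DICOM series or NIfTI volumes are
    anonymized, split into axial slices, intensity-windowed and embedded
    with a pluggable feature extractor; a from-scratch K-means classifier
    (k = 2) then separates tumor-level slices from irrelevant ones and the
    pipeline emits sorted PNG folders plus a CSV classification manifest.
    Includes the standard binary evaluation indexes (sensitivity,
    specificity, false positive/negative rate, accuracy), a synthetic
    CT-phantom cohort generator with per-slice ground truth so every stage
    is testable offline, and a desk-scale stochastic-gradient-descent
    classifier demo for comparing filtered against unfiltered training
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
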