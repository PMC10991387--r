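Package: ccanet
Title: Brain-Behaviour Canonical Correlation Analysis of Cerebellar-Cerebral
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for relating cerebellar-cerebral functional
    connectivity to behaviour in neurodevelopmental cohorts: scan-level motion
    quality control, Fisher-z partial-correlation network features under a
    48-label parcellation, empirical-Bayes site harmonization, correlation-
    thresholded canonical correlation analysis with permutation significance and
    Procrustes-aligned bootstrap stability, spectral clustering of subject
    loadings, and cross-cohort replication scoring of coefficient vectors.
    Includes a synthetic-cohort generator with planted canonical components so
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
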