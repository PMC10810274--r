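Package: enoseid
Title: Human Identification from Electronic-Nose Body-Odor Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for closed-set human identification from metal-oxide
    electronic-nose (eNose) measurements of body odor. Provides a canonical
    endpoint-table data model with CSV readers and writers, fresh-control
    drift correction by reference-odorant division, k-nearest-neighbour and
    regularized linear discriminant classifiers with fully specified
    deterministic behaviour, within-day, accumulated-day and across-day
    cross-validation designs, permutation-null and exact binomial
    significance tests, and a synthetic-cohort generator that emulates a
    multi-day, multi-region, dual-device sampling design with configurable
    sensor drift, so that every stage of the pipeline can be exercised with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
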