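Package: metaqtl
Title: Meta-QTL Analysis on a Consensus Genetic Map
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of published quantitative trait loci
    (QTL) in durum wheat and related crops. Projects heterogeneous QTL from
    their original study maps onto a consensus genetic map by homothetic
    (two-anchor affine) transfer, re-estimates 95% confidence intervals from
    population size, type and phenotypic variance explained, clusters the
    projected QTL per chromosome into meta-QTL under a Gaussian mixture with
    known per-QTL variances fitted by EM, selects the number of components by
    vote among AIC, corrected AIC, BIC and AWE, applies Loeffler-style
    promising-MQTL selection and a physical-distance filter, and screens
    candidate genes in the marker-anchored physical intervals by transposable
    element exclusion and expression thresholds. Ships a synthetic-data
    generator with planted ground truth and transcriptions of the reference
    study's summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
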