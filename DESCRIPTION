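Package: dartkin
Title: Fingerprinting, Kinship and Ploidy-Aware Parentage for Clonal
    Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing germplasm collections genotyped with
    dominant presence/absence markers (such as DArT) and codominant SSR
    profiles.  Computes pairwise Jaccard similarity with calibrated
    thresholds to detect clones, duplicates and relationships closer than
    first degree; verifies parentage across ploidy levels, including
    triploids formed by unreduced (first-division-restitution) gametes and
    tetraploids formed by triploid gametes, with exclusion-based inference
    of missing parents; selects cluster numbers from replicate Bayesian
    clustering runs by the Evanno delta-K statistic; and simulates
    pedigreed collections with planted truth so every stage of the
    analysis can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
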