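Package: salivemo
Title: Salivary Biomarker Profiling of Fragrance-Induced Emotions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for decoding emotional responses to olfactory
    stimulation from multiplex salivary biomarker panels (alpha-amylase,
    cortisol, DHEA, oxytocin). Covers synthetic cohort simulation with
    circadian drift and assay noise, post/pre-stimulation ratio computation
    and three-state discretization into 81 biomarker profiles, per-fragrance
    hierarchical k-means clustering with Calinski-Harabasz model selection,
    a from-scratch CART classifier over discrete biomarker states with rule
    extraction, fragrance-level emotional signatures, implicit association
    test scoring, and cross-method concordance statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
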