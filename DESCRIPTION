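Package: drmsim
Title: Similarity-Driven DRM List Generation and False-Memory Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying false recognition in the
    Deese-Roediger-McDermott (DRM) paradigm with vector-space models of
    prior knowledge. Provides embedding-space containers with word2vec-style
    text I/O, prototype (centroid) construction and cosine-similarity
    primitives; a similarity-driven DRM list generator (spherical k-means
    partitioning, close/far candidate pools, centroid-near lure selection)
    that annotates every lure with vision-based and language-based
    similarity to the studied-set centroid; a calibrated generator of
    coupled vision/language embedding spaces and simulated recognition
    responses; binomial generalized linear mixed models with crossed
    participant and list random intercepts, hierarchical AIC comparison
    with Akaike weights, odds ratios with Wald intervals and collinearity
    diagnostics; and signal-detection descriptives (hit and false-alarm
    rates, A-prime) with compliance-based participant exclusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tibble,
    withr
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
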