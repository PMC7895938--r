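Package: thermevol
Title: Tempo and Mode of Thermal Tolerance Limit Evolution on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Maximum-likelihood fitting and comparison of Brownian-motion,
    Ornstein-Uhlenbeck and white-noise models of continuous trait evolution on
    time-calibrated phylogenies, aimed at comparative analyses of upper and
    lower thermal tolerance limits. Provides exact likelihoods with dual
    evaluation paths (dense multivariate normal and Felsenstein pruning),
    Brownian rate (tempo, sigma^2) and attraction-strength (mode, -log alpha)
    estimation with multi-tree summaries, ancestral-state reconstruction and
    traitgram export, palaeoclimate-origin assignment of taxonomic orders with
    cold- versus warm-origin contrasts, random-forest variable-importance
    analysis of thermal-limit predictors, and a seeded synthetic-data generator
    that emulates species-level thermal-limit tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
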