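Package: nitroregime
Title: Functional Regimes of Soil Nitrate Reduction Under pH Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models nitrate reduction dynamics of soil microbial communities
    subjected to short-term pH perturbations. Provides a two-resource
    consumer-resource model of nitrate and a growth-limiting nutrient, least
    squares fitting of paired chloramphenicol-treated and untreated nitrate
    time series, classification of the fitted conditions into three
    functional regimes (acidic death, nutrient limitation, resurgent
    growth), titration-curve dose/pH conversion and regime-boundary trend
    analysis, spike-in based absolute abundance with an empirically
    calibrated replicate noise model and z-score enrichment calling,
    rank-2 non-negative matrix factorization of phylum-level growth folds,
    LASSO prediction of soil native pH from resurgent-growth taxa, and a
    deterministic synthetic-data generator emulating the full microcosm
    panel design for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    glmnet,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
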