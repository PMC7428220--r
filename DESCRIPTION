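Package: raretrends
Title: Trends in Local Rarity from Assemblage Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying temporal change in the number of locally rare
    species across ecological assemblage time series. Provides sample-based
    rarefaction that equalizes the number of whole sampling occasions across
    years, per-year rarity metrics (singletons, singletons plus doubletons,
    Fisher's log-series alpha) alongside species richness and assemblage size,
    negative-binomial and Gaussian mixed-effect trend models with random slopes
    per assemblage, Pearson correlation of per-assemblage trend slopes with a
    drop-a-fraction resampling sensitivity analysis, and a runs-test-gated
    classification of rare-species populations into persistent, immigration,
    extinction and multiple-event categories. A synthetic-data generator with
    known ground truth emulates multi-assemblage count data under contrasting
    processes of rarity change (population decline with or without local
    extinction, and immigration), so the full pipeline is testable without any
    external database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmmTMB,
    jsonlite,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
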