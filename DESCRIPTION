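Package: frugalcast
Title: Fast-and-Frugal Tree Forecasts of Regional Crop Production from
    Climate Variability Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Translates large-scale climate-variability indices (SOI, NAO,
    EA, EA/WR, SCA) into binary high/low crop-production forecasts per
    region and lead time. Implements three-month lead-time index features,
    proportional gap-filling of regional production records from national
    totals, trend-aware production anomaly binarization, a from-scratch
    fast-and-frugal decision-tree learner (the ifan cue-ranking algorithm
    with balanced-accuracy threshold selection), fan-based ROC/AUC by the
    trapezoidal rule, train/test validation with pruning selection,
    bootstrap significance per region, binomial field significance across
    regions, and a seeded synthetic-data generator that couples index
    panels to production so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
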