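Package: runsit
Title: Mining Temporal and Environmental Situations Associated with Running Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-data-driven pipeline for studying which
    temporal, weather-related, topographical and demographical situations are frequently
    associated with above- or below-average running distance. Provides a synthetic world
    and runner-population generator with planted situation effects, a 100 m analysis grid
    with per-landuse-class distance and coverage rasters and national-quantile binning,
    run cleaning and per-user distance normalization, dynamic-time-warping distances
    between 52-week activity sequences with Ward agglomerative clustering, and weighted
    frequent itemset mining (a signed-weight FP-growth) with per-feature variability
    statistics, value histograms and top-situation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
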