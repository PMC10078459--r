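Package: ringdisc
Title: Least-Cost Optimality Prediction of Tree-Ring Carbon Isotope Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling of leaf-level carbon isotope discrimination
    (Delta13C) from summer climate with the least-cost optimality stomatal
    model, including photorespiratory and mesophyll effects; conversion of
    tree-ring delta13C chronologies to Delta13C (removal of applied Suess
    corrections, post-photosynthetic fractionation); and model-data
    comparison statistics for multi-site networks (offsets, Spearman rank
    correlation, inter-annual variability, paired signed-rank tests, OLS
    trends, composite chronologies and environmental-attribution
    regressions). Includes a seeded synthetic-network generator so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
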