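Package: stcrqa
Title: Spatio-Temporal Cross-Recurrence Analysis of Multi-Station
    Water-Quality Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic coupling analysis for synchronously sampled
    environmental sensor series from several monitoring stations.
    Reconstructs each series in phase space (delay selected by the first
    minimum of average mutual information, dimension by false nearest
    neighbours), builds cross-recurrence plots between factor pairs under
    a shared embedding, quantifies them with recurrence rate, determinism,
    laminarity and mean diagonal line length, adds histogram-based mutual
    information, and fuses the five indices into a normalized
    geometric-mean coupling score with per-target ranking panels and a
    data-length sensitivity analysis. Includes a seeded generator of
    coupled multi-station surrogate series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
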