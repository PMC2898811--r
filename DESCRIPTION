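Package: eventclust
Title: Exact Tests for Geographic Aggregations of Disease-Related Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects geographic aggregations (clusters) of repeated
    disease-related events, such as emergency-department presentations,
    across administrative areas. Each area is tested by combining it with
    its nearest neighbours until a prescribed cluster size is reached, in
    the style of the Besag-Newell test, and the significance of the
    combined count is evaluated exactly. Four null models are provided:
    the hypergeometric test on case counts, an exact multiple
    hypergeometric test on event counts when the number of events per
    case is known, a compound Poisson event test, and an occupancy-number
    test when only aggregate event totals are available. Stratified
    variants adjust for population composition, a sequential prescription
    chooses per-cell cluster sizes, and Monte Carlo simulation assesses
    overall clustering and empirical Type I error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    geosphere,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
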