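Package: holcmatch
Title: Propensity-Matched Analysis of Historical HOLC Grades and Birth Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for studying the
    association between historical Home Owners' Loan Corporation (HOLC)
    "Security Map" neighborhood grades and perinatal outcomes. Provides a
    synthetic city and birth-cohort simulator with configurable injected grade
    effects and 1940s-census confounding; point-in-polygon grade assignment
    with an explicit inclusion/exclusion flow; areal apportionment of
    count-valued 1940 census tract metrics onto HOLC polygons; coding of seven
    binary perinatal outcomes (preterm, very preterm, low and very low birth
    weight, small-for-gestational-age, perinatal and neonatal mortality);
    cross-validated stacked-ensemble propensity scores for adjacent-grade
    contrasts with percentile support trimming; optimal full matching with
    replacement under a propensity caliper and Mahalanobis within-caliper
    distance; and weighted balance tests plus cluster-robust weighted logistic
    outcome models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    glmnet,
    splines
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich
Config/testthat/edition: 3
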