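Package: mealmetry
Title: Image-Based Meal Volume and Nutrient Estimation with a Reference-Card
    Metric Anchor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-item food volume from depth-annotated meal images
    using a reference card of known physical size as the metric anchor, maps
    volumes to energy and macronutrients through nutrient tables with
    primary/secondary fallback, and evaluates daily intake estimates against
    reference intakes with mean absolute percentage error and Bland-Altman
    agreement statistics. Two depth back-ends are supported: a pluggable
    single-image depth provider rescaled by the card, and a two-view
    geometry back-end (rectification, block matching, disparity to depth).
    A synthetic tabletop-scene renderer with analytic ground-truth volumes
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
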