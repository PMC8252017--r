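Package: lagoceiling
Title: Competitive Ceilings on Lagomorph Body-Size Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for asking why lagomorph (rabbit, hare, pika) body size is
    bounded from above. Fits phylogenetic generalized least squares (Pagel's
    lambda) allometries of population density and basal metabolic rate,
    composes them into local-population energy-use scaling lines, solves for
    the equilibrial body mass at which the lagomorph and ungulate lines cross
    and for energy-equivalent body masses, estimates fossil body masses from
    dental and mandibular measurements with phylogenetic covariance and
    intraspecific variation, builds per-bin fossil time series (range-through
    occupancy, guild extrema, sampling probability, proxy alignment, the
    competitive-ceiling predictor), and compares autocovariate regression
    models of maximum lagomorph body mass by AICc with Monte-Carlo
    propagation of locality-age and body-mass uncertainty. A synthetic-data
    module generates trees, traits, fossil records and ecoregion tables with
    known ground truth so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
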