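Package: adexpose
Title: Television Food-Advertising Exposure Estimation from People-Meter Panels
Version: 0.1.0
Authors@R:
    person("Ad", "Exposure Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating population exposure to televised food and
    beverage advertising from ad-occurrence logs and a people-meter viewership
    panel. Computes post-stratification weights, impressions, gross rating
    points (GRPs) and per-capita ads/person/year by age group, station, food
    category, marketing technique and nutritional healthfulness; classifies
    advertised products against configurable nutrient-profile thresholds;
    manages content-analysis codings with inter-rater reliability statistics;
    and assembles child-versus-adolescent difference tables. Includes a
    synthetic-market simulator with brute-force ground truth for validating
    the panel-based estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
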