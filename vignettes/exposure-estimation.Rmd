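---
title: "Estimating television food-advertising exposure from a people-meter panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating television food-advertising exposure from a people-meter panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adexpose)
library(data.table)
```

## The measurement problem

Public-health surveillance of food marketing asks a deceptively simple
question: how many televised food and beverage advertisements does an
average child see in a year, and how does that compare with an average
adolescent? Neither quantity is directly observable. What can be observed
are two administrative data streams:

* an **ad-occurrence log** — every airing of every food-ad creative on the
  market's stations, with station, timestamp and a creative identifier; and
* a **people-meter panel** — a stratified sample of individuals wearing
  portable meters that record which station the nearby television set is
  tuned to, and when.

`adexpose` combines the two into per-capita exposure via **gross rating
points**. A panel member registers an *impression* for an airing when they
have a viewing interval on the airing's station covering its start
instant. With post-stratification weights \(w_m\) (persons represented by
member \(m\)) and capped product weights \(q_a = \min(\max(p_a, 1), 3)\)
for an ad featuring \(p_a\) distinct products,

\[
\mathrm{GRP}_g \;=\; \frac{\sum_{m \in g}\sum_{a} \mathbf{1}\{m \text{ tuned at } a\}\, w_m\, q_a}{N_g} \times 100,
\qquad
\mathrm{exposure}_g \;=\; \mathrm{GRP}_g / 100 ,
\]

where \(N_g\) is the group's market population. Exposure is therefore the
estimated average number of advertised food products viewed per person
over the period. Impressions are product-weighted so that the tables count
food products, consistent with the weighted-frequency convention in which
an ad with 2 products aired 500 times has weighted frequency 1000, and the
product multiplier is capped at 3 (4 products × 500 airings → 1500).

This is a *proximity* measure: the meter shows the set was tuned while the
panelist was near it, not that the ad was attentively watched. All
downstream numbers inherit that caveat.

## Weighting

Panelists are weighted by post-stratification over age group × sex ×
household-size band: the weight of each member is the population of their
demographic cell divided by the number of panelists in it, so weights sum
to the market population. When a populated cell has no panelists the
partition is coarsened — household-size cells collapse within the age ×
sex block, then sex within age — keeping the weighting a true partition
(weights still sum to the population). An age group with population but no
panelists at all is an error rather than a silent extrapolation.

Per-capita exposure is invariant to the overall population scale: doubling
every cell population doubles every weight and the denominator alike. The
simulator exploits this by running at a few-thousand-person scale.

## Conventions that matter

* **Unique ad** = distinct (creative content, language, duration) triple;
  deduplication keeps the first occurrence and is idempotent.
* **Viewing intervals** are half-open \([start, end)\); an airing at the
  exact end instant of an interval is *not* an impression. Splitting an
  interval into contiguous sub-intervals changes nothing.
* **Impression trigger** is the airing's start instant only; partial
  exposure to an ad is not prorated. Minute-level people-meter semantics
  make anything finer spurious.
* **Brand ads** (no identifiable product) count 1 unit per airing in the
  frequency grand total but appear in no category row and are never
  classified nutritionally — their content cannot be categorised.
* **Multi-category ads** contribute their per-category distinct-product
  count (capped at 3 per row) to each category they touch, while the grand
  total counts the ad once at its overall capped weight. Category rows can
  therefore sum to *more* than the total row — the same structural
  super-additivity seen in published category tables — and station rows,
  being a true partition, sum to it exactly.
* **Differences** are adolescent − child in absolute terms, and that
  difference divided by the *child* exposure (×100) in relative terms.
  The child-denominator convention is the one that reproduces every
  published difference figure we re-derive arithmetically, and is applied
  to unrounded aggregates; rounding (half away from zero, 1 decimal) comes
  last. Daily rates divide annual exposure by 365.

## Nutrient-profile classification

Products are labelled against configurable thresholds on saturated fat,
sugars and sodium, each gated by an added-ingredient flag: a product is
*unhealthy* iff any gated nutrient **strictly** exceeds its limit (equality
is compliant). An ad is unhealthy if *any* featured product is unhealthy —
including products beyond the 3-product weighting cap, since the rule is
about ad content, not weighting — healthy if at least one product is
classifiable and none unhealthy, and unclassified otherwise. Shares are
reported over classified frequency only, with the unclassified fraction
alongside.

Two deliberate design points:

* Threshold *values* live in versioned JSON config
  (`inst/extdata/npm_thresholds_synthetic.json`), not in code. The shipped
  numbers (2 g saturated fat, 5 g sugars, 200 mg sodium per serving) are a
  **synthetic stand-in** chosen to be order-of-magnitude plausible for a
  per-serving basis; regulator-published criteria should be transcribed
  into a config of the same shape for real analyses.
* The config carries an explicit `basis` (`per_serving` here). Profiles on
  a different basis raise an error rather than being converted silently,
  because the main classification texts often leave the basis implicit.

Nutrition is resolved through a provenance cascade — packaged-food label
database, restaurant-menu database, company Canadian site, online
nutrition-facts tables, company US site, similar-product substitute — and
the first tier containing the product wins; the tier is recorded so the
share of low-provenance data is auditable.

## Content analysis of marketing techniques

The 22-technique codebook (child/teen actors, language, themes,
spokes-characters, licensed characters, cross-promotions, incentives,
contests, celebrity endorsement, health claims, price promotions, online
calls to action) records each technique present/absent **once per ad**,
regardless of product count. The module assigns ads to coders in
near-equal random blocks, computes inter-rater reliability, and collapses
multiple codings by per-technique majority vote with exact ties flagged
`pending` for human settlement — a deterministic stand-in for the
researcher-led consensus step of a real coding exercise.

Reliability is reported as *percent agreement* (item-level identity of the
full technique vector, plus per-technique rates) and as *mean pairwise
Cohen's kappa*, always labelled: a single headline reliability figure is
not interpretable without knowing which statistic produced it, so the
package never emits an unlabelled one. Degenerate kappa (both coders
constant and identical) is defined as 1.

## The synthetic market

Licensed airing and viewership data cannot be redistributed, so the
package ships a generator whose *defaults state the world the estimator is
meant for*: 36 stations, a 365-day window, a panel of 175 children /
106 adolescents (plus 150 other panelists), 57 fine food categories
aggregated onto 13 coarse ones, a category mix dominated by restaurant
advertising (~49%), technique prevalences matching a full-year coded
market, multi-product ads, and a product pool in which most products
(probability 0.8) exceed at least one threshold. Where no source states a
value the choice was made once and documented here:

* market population 24,000 (4,000 children / 2,600 adolescents / 17,400
  other) — a computational scale choice, legitimate because per-capita
  exposure is scale-invariant (above);
* products per ad `P(1..5) = .55, .20, .15, .07, .03`; 3% brand ads;
  30% of products missing from every nutrition source (the real study
  could not classify half its ad frequency, concentrated in brand ads and
  sit-down restaurants);
* ~90 food-ad airings/station/day, sized so a full-year market carries
  roughly the observed weighted frequency;
* viewing: per person-day session counts are Poisson (≈2/day), session
  starts uniform over the 24 h, durations exponential truncated at the
  next session and midnight, stations drawn from age-group preference
  weights. Mean daily viewing ≈148 min for children and ≈119 min for
  adolescents (the 17.3 vs 13.9 h/week ordering that drives children's
  higher overall exposure). The true device-level viewing process of a
  commercial panel is not public; this model is a stand-in that induces
  realistic group differences, not a claim about panel methodology.

All randomness flows from one master seed through named substreams
(`stations`, `products`, `nutrition`, `ads`, `codings`, `airings`,
`viewing`, `panel`), so regeneration is bit-identical and each stage is
independently reproducible.

**Ground truth.** The generator materialises the *entire* synthetic
population's viewing and computes exact exposure by exhaustive counting
(`compute_ground_truth()`), via station/day-bucketed scans that share no
code with the estimator's non-equi join. Two validations follow:

1. *Exactness*: with the panel set to the whole population at unit
   weights, the estimator reproduces ground truth to machine precision.
2. *Calibration*: holding one market fixed (population ~10,000, ~5,000
   airings over 30 days) and redrawing the 300-person stratified panel
   120 times, the mean panel estimate sits within 2 standard errors of
   ground truth for both age groups. The panel draw is the randomness
   being tested; regenerating whole markets per replicate would multiply
   runtime without sharpening the question the test asks.

A green synthetic suite establishes that the *estimator* is correct and
unbiased under the stated world. It does not establish anything about real
viewing behaviour: the generator has no program schedules, no co-viewing,
no seasonal structure, no correlation between ad content and time of day,
and its nutrition values are draws around synthetic thresholds.

## Numerical and degenerate-input choices

* Weighted frequency of a brand ad is 1 per airing (documented choice; the
  published grand total does not state its brand convention).
* Relative difference with a zero child denominator is flagged
  `relative_undefined`, never `Inf`.
* Healthfulness shares with zero classified frequency error out rather
  than returning `NaN`.
* Product counts are over *distinct* products: duplicating a product row
  changes no weight, no category slice and no technique slice.
* Rounding is half away from zero, applied once after all aggregation;
  report files round-trip exactly at the written precision.
* Timestamps are naive local station time (no DST modelling); sessions are
  generated within-day, and the ground-truth bucketing nevertheless
  handles intervals that cross midnight.

## Limitations

Exposure is tuned-set proximity, not attention. The product-weighted
impression convention is one of two defensible readings of a
"food products viewed" table; it is isolated in `capped_product_weight()`
and the slice builders, so an airing-weighted variant is a one-line
change. The synthetic thresholds and the viewing-session model are
explicitly not re-creations of their proprietary counterparts, and
percentile-level agreement with any published exposure table is out of
scope — the package validates arithmetic identities exactly and the
estimator statistically.
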