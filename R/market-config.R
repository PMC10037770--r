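#' Default population by stratum
#'
#' A down-scaled market population (24,000 persons) split over age group x
#' sex x household-size band. Per-capita exposure is invariant to the
#' population scale (weights and population cancel in the GRP), so the
#' simulator uses a population small enough that exhaustive ground truth
#' stays computable; the panel-to-population ratios, not the absolute
#' counts, are what matter.
#'
#' @return `data.table`: `age_group`, `sex`, `hh_band`, `population`.
#' @export
default_population <- function() {
  cells <- CJ(age_group = c("child_2_11", "adolescent_12_17", "other"),
              sex = c("f", "m"), hh_band = c("hh_1_2", "hh_3plus"))
  totals <- c(child_2_11 = 4000, adolescent_12_17 = 2600, other = 17400)
  cells[, population := totals[age_group] / 4]
  cells[]
}

#' Default panel sizes by stratum
#'
#' 175 children (2-11), 106 adolescents (12-17) and 150 other panelists,
#' allocated over sex x household-size cells by largest remainder.
#'
#' @return `data.table`: `age_group`, `sex`, `hh_band`, `n`.
#' @export
default_panel_sizes <- function() {
  cells <- CJ(age_group = c("child_2_11", "adolescent_12_17", "other"),
              sex = c("f", "m"), hh_band = c("hh_1_2", "hh_3plus"))
  totals <- c(child_2_11 = 175L, adolescent_12_17 = 106L, other = 150L)
  out <- cells[, .(sex = sex, hh_band = hh_band,
                   n = allocate_integer(totals[[age_group[1]]], .N)),
               by = age_group]
  out[]
}

# split total into k integers differing by <= 1 (largest remainder)
allocate_integer <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + as.integer(seq_len(k) <= extra)
}

#' Default coarse-category airing mix
#'
#' Weighted-frequency shares by coarse category observed in a full-year
#' 36-station market (restaurants dominate at just under half), normalized
#' to sum to one.
#'
#' @return Named numeric over the 13 coarse categories, summing to 1.
#' @export
default_category_mix <- function() {
  mix <- c(bread = 0.7, sweet_baked = 3.6, candy_chocolate = 9.0,
           breakfast = 6.2, dairy = 8.4, condiments = 1.3, entrees = 3.5,
           fruits_vegetables = 1.6, beverages = 5.2, miscellaneous = 4.1,
           snacks = 9.0, water = 0.8, restaurants = 49.1)
  mix / sum(mix)
}

#' Default viewing-model parameters
#'
#' Mean daily viewing of roughly 148 min for children (17.3 h/week) and
#' 119 min for adolescents (13.9 h/week), 180 min for other panelists;
#' about two sessions per day; and a station-preference concentration
#' (gamma shape) controlling how skewed each group's station choices are
#' (smaller = more concentrated on a few stations).
#'
#' @return Named list by age group with `mean_daily_minutes`,
#'   `sessions_per_day`, `station_concentration`.
#' @export
default_viewing_params <- function() {
  list(
    child_2_11       = list(mean_daily_minutes = 148, sessions_per_day = 2.0,
                            station_concentration = 0.5),
    adolescent_12_17 = list(mean_daily_minutes = 119, sessions_per_day = 2.0,
                            station_concentration = 0.5),
    other            = list(mean_daily_minutes = 180, sessions_per_day = 2.5,
                            station_concentration = 1.0)
  )
}

#' Synthetic-market configuration
#'
#' Describes a television advertising market and its viewing panel. The
#' defaults state a full-year market in the shape of the studied one: 36
#' stations, 365 days, a panel of 175 children / 106 adolescents, 57 fine
#' food categories aggregating to 13, a category mix dominated by
#' restaurant advertising, multi-product ads, and a product pool in which
#' most products exceed at least one nutrient threshold.
#'
#' @param n_stations stations in the market (>= 1).
#' @param n_days days in the study window (>= 1).
#' @param population_by_stratum data.frame `age_group`, `sex`, `hh_band`,
#'   `population`.
#' @param panel_size_by_stratum data.frame `age_group`, `sex`, `hh_band`,
#'   `n`; elementwise `<=` population.
#' @param category_mix named airing proportions over the coarse categories
#'   (must sum to 1).
#' @param products_per_ad_dist named probabilities over product counts per
#'   ad (`"1"`, `"2"`, ...).
#' @param p_exceeds_threshold probability a generated product exceeds at
#'   least one nutrient threshold.
#' @param p_missing_nutrition probability a product is absent from every
#'   nutrition source.
#' @param p_brand_ad probability an ad is a brand ad (no products).
#' @param n_unique_ads unique creatives in the market.
#' @param airings_per_station_day mean food-ad airings per station per day.
#' @param viewing_model_params per-age-group viewing parameters, see
#'   [default_viewing_params()].
#' @param thresholds nutrient-threshold config used when generating
#'   product nutrition (see [npm_thresholds()]).
#' @param seed master seed; all stages derive named substreams from it.
#' @return Validated list of class `market_config`.
#' @export
market_config <- function(n_stations = 36L,
                          n_days = 365L,
                          population_by_stratum = default_population(),
                          panel_size_by_stratum = default_panel_sizes(),
                          category_mix = default_category_mix(),
                          products_per_ad_dist = c(`1` = 0.55, `2` = 0.20,
                                                   `3` = 0.15, `4` = 0.07,
                                                   `5` = 0.03),
                          p_exceeds_threshold = 0.8,
                          p_missing_nutrition = 0.3,
                          p_brand_ad = 0.03,
                          n_unique_ads = 1387L,
                          airings_per_station_day = 90,
                          viewing_model_params = default_viewing_params(),
                          thresholds = npm_thresholds(),
                          seed = 1L) {
  cfg <- structure(
    list(n_stations = as.integer(n_stations), n_days = as.integer(n_days),
         population_by_stratum = as.data.table(population_by_stratum),
         panel_size_by_stratum = as.data.table(panel_size_by_stratum),
         category_mix = category_mix,
         products_per_ad_dist = products_per_ad_dist,
         p_exceeds_threshold = p_exceeds_threshold,
         p_missing_nutrition = p_missing_nutrition,
         p_brand_ad = p_brand_ad,
         n_unique_ads = as.integer(n_unique_ads),
         airings_per_station_day = airings_per_station_day,
         viewing_model_params = viewing_model_params,
         thresholds = thresholds,
         seed = as.integer(seed)),
    class = "market_config")
  validate_market_config(cfg)
}

#' Validate a market configuration
#'
#' Checks the configuration invariants, naming the offending field in the
#' error.
#'
#' @param config a `market_config` list.
#' @return The config, invisibly-validated (returned).
#' @export
validate_market_config <- function(config) {
  fail <- function(field, msg) stop("invalid market config [", field, "]: ",
                                    msg, call. = FALSE)
  if (config$n_stations < 1L) fail("n_stations", "must be >= 1")
  if (config$n_days < 1L) fail("n_days", "must be >= 1")
  mix <- config$category_mix
  if (is.null(names(mix)) ||
      !setequal(names(mix), coarse_categories()))
    fail("category_mix", "must name all 13 coarse categories")
  if (abs(sum(mix) - 1) > 1e-8) fail("category_mix", "must sum to 1")
  if (any(mix < 0)) fail("category_mix", "proportions must be >= 0")
  dist <- config$products_per_ad_dist
  if (abs(sum(dist) - 1) > 1e-8 || any(dist < 0))
    fail("products_per_ad_dist", "must be a probability distribution")
  if (is.null(names(dist)) || anyNA(as.integer(names(dist))))
    fail("products_per_ad_dist", "names must be product counts")
  for (p in c("p_exceeds_threshold", "p_missing_nutrition", "p_brand_ad"))
    if (config[[p]] < 0 || config[[p]] > 1) fail(p, "must be in [0, 1]")
  if (config$n_unique_ads < 1L) fail("n_unique_ads", "must be >= 1")
  if (config$airings_per_station_day < 0)
    fail("airings_per_station_day", "must be >= 0")
  pop <- config$population_by_stratum
  pan <- config$panel_size_by_stratum
  key <- c("age_group", "sex", "hh_band")
  if (!all(c(key, "population") %in% names(pop)))
    fail("population_by_stratum", "needs age_group, sex, hh_band, population")
  if (!all(c(key, "n") %in% names(pan)))
    fail("panel_size_by_stratum", "needs age_group, sex, hh_band, n")
  m <- merge(pop, pan, by = key, all = TRUE)
  m[is.na(m)] <- 0
  if (any(m$n > m$population))
    fail("panel_size_by_stratum",
         "panel exceeds population in strata: " %+%
           paste(head(stratum_key(m$age_group, m$sex, m$hh_band)[m$n > m$population], 3L),
                 collapse = ", "))
  ages <- unique(pop$age_group)
  vp <- config$viewing_model_params
  if (!all(ages %in% names(vp)))
    fail("viewing_model_params",
         "missing age groups: " %+% paste(setdiff(ages, names(vp)), collapse = ", "))
  config
}

`%+%` <- function(a, b) paste0(a, b)
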