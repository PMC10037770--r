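# small but fully featured market used by several tests
small_config <- function(seed = 1L, ...) {
  s <- make_strata(child_pop = 200, adol_pop = 120, other_pop = 80,
                   child_n = 20, adol_n = 12, other_n = 8)
  args <- list(n_stations = 3L, n_days = 5L,
               population_by_stratum = s$population,
               panel_size_by_stratum = s$panel_sizes,
               n_unique_ads = 60L, airings_per_station_day = 12,
               seed = seed)
  do.call(market_config, utils::modifyList(args, list(...)))
}

test_that("invalid configurations are rejected with the field named", {
  expect_error(small_config(n_stations = 0L), "n_stations")
  expect_error(small_config(n_days = 0L), "n_days")
  bad_mix <- default_category_mix(); bad_mix["snacks"] <- bad_mix["snacks"] + 0.5
  expect_error(small_config(category_mix = bad_mix), "category_mix")
  expect_error(small_config(p_brand_ad = 1.5), "p_brand_ad")
  expect_error(small_config(products_per_ad_dist = c(`1` = 0.4, `2` = 0.4)),
               "products_per_ad_dist")
  s <- make_strata(child_pop = 4, adol_pop = 4, child_n = 8, adol_n = 4)
  expect_error(market_config(population_by_stratum = s$population,
                             panel_size_by_stratum = s$panel_sizes),
               "panel_size_by_stratum")
})

test_that("regeneration with the same seed is bit-identical", {
  m1 <- generate_market(small_config(seed = 42L))
  m2 <- generate_market(small_config(seed = 42L))
  for (part in c("ads", "ad_products", "airings", "panel", "viewing",
                 "codings", "products"))
    expect_identical(as.data.frame(m1[[part]]), as.data.frame(m2[[part]]),
                     info = part)
  expect_identical(m1$truth$by_group, m2$truth$by_group)
  m3 <- generate_market(small_config(seed = 43L))
  expect_false(identical(as.data.frame(m1$airings),
                         as.data.frame(m3$airings)))
})

test_that("generated market is referentially consistent", {
  m <- generate_market(small_config(seed = 2L))
  expect_true(all(m$airings$ad_id %in% m$ads$ad_id))
  expect_true(all(m$viewing$member_id %in% m$panel$member_id))
  expect_true(all(m$viewing$station %in% m$stations))
  expect_true(all(m$ad_products$product_id %in% m$products$product_id))
  expect_true(all(m$ads$n_products[m$ads$is_brand] == 0L))
  # panel weights reconstruct the population
  expect_equal(sum(m$panel$weight),
               sum(m$config$population_by_stratum$population))
  # airings fall inside the study window
  expect_true(all(m$airings$start >= as.POSIXct("2019-01-01", tz = "UTC")))
  expect_true(all(m$airings$start <
                    as.POSIXct("2019-01-01", tz = "UTC") + 5 * 86400))
  validate_viewing(m$population_viewing)
  succeed()
})

test_that("full-coverage market: everyone sees every airing at capped weight", {
  s <- make_strata(child_pop = 8, adol_pop = 4, child_n = 8, adol_n = 4)
  ads <- data.table::data.table(ad_id = "a", content_key = "k",
                                language = "en", duration = 15L,
                                n_products = 4L, is_brand = FALSE)
  airings <- data.table::data.table(station = "S01", start = T0 + 3600,
                                    ad_id = "a")
  persons <- s$population[rep(seq_len(nrow(s$population)),
                              s$population$population)]
  persons[, person_id := sprintf("p%03d", .I)]
  viewing <- data.table::data.table(member_id = persons$person_id,
                                    station = "S01", start = T0,
                                    end = T0 + 86400)
  gt <- compute_ground_truth(airings, viewing, ads, persons)
  expect_equal(unname(gt$by_group), c(3, 3)) # min(4 products, 3) each
  # zero airings -> zero exposure everywhere
  gt0 <- compute_ground_truth(airings[0], viewing, ads, persons)
  expect_equal(unname(gt0$by_group), c(0, 0))
})

test_that("1 person, 1 airing worked examples", {
  persons <- data.frame(person_id = "p1", age_group = "child_2_11")
  ads <- data.frame(ad_id = "a", n_products = 2L)
  airings <- data.frame(station = "S", start = T0 + 100, ad_id = "a")
  watched <- data.frame(member_id = "p1", station = "S",
                        start = T0, end = T0 + 200)
  expect_equal(unname(compute_ground_truth(airings, watched, ads,
                                           persons)$by_group), 2)
  away <- data.frame(member_id = "p1", station = "S",
                     start = T0 + 150, end = T0 + 400)
  expect_equal(unname(compute_ground_truth(airings, away, ads,
                                           persons)$by_group), 0)
})

test_that("ground truth sums over station slices and matches the double-loop oracle", {
  m <- generate_market(small_config(seed = 3L))
  gt <- m$truth
  sums <- tapply(gt$by_group_station$exposure, gt$by_group_station$group, sum)
  expect_equal(as.numeric(sums[names(gt$by_group)]),
               unname(gt$by_group), tolerance = 1e-12)

  # independent pure-R oracle on a subsample of airings and persons
  sub_air <- m$airings[1:15]
  keep <- m$persons$person_id[seq(1, nrow(m$persons), by = 20)]
  sub_persons <- m$persons[m$persons$person_id %in% keep]
  sub_view <- m$population_viewing[member_id %in% keep]
  gt_sub <- compute_ground_truth(sub_air, sub_view, m$ads, sub_persons)
  unit_panel <- data.table::data.table(
    member_id = sub_persons$person_id, age_group = sub_persons$age_group,
    sex = sub_persons$sex, hh_band = sub_persons$hh_band, weight = 1)
  want <- oracle_impressions(sub_air, m$ads, sub_view, unit_panel)
  pop <- gt_sub$population_by_group
  for (g in names(want))
    expect_equal(gt_sub$by_group[[g]], want[[g]] / pop[[g]], info = g)
})

test_that("estimator equals ground truth when panel = population, weights 1", {
  m <- generate_market(small_config(seed = 4L))
  persons <- m$persons
  full_panel <- data.table::data.table(
    member_id = persons$person_id, age_group = persons$age_group,
    sex = persons$sex, hh_band = persons$hh_band, weight = 1)
  led <- count_impressions(m$airings, m$ads, m$population_viewing,
                           full_panel)
  pop <- m$truth$population_by_group
  est <- estimate_exposure(led, pop, "total")
  expect_equal(setNames(est$exposure, est$group),
               m$truth$by_group[est$group])
  st <- estimate_exposure(led, pop, "station")
  gt_st <- m$truth$by_group_station
  merged <- merge(as.data.frame(st), as.data.frame(gt_st),
                  by.x = c("group", "slice"), by.y = c("group", "station"))
  expect_equal(merged$exposure.x, merged$exposure.y)
})

test_that("panel resampling varies by seed but stays near truth on average", {
  m <- generate_market(small_config(seed = 5L))
  pop <- m$truth$population_by_group
  est_one <- function(s) {
    p <- resample_panel(m, s)
    led <- count_impressions(m$airings, m$ads, p$viewing, p$panel)
    e <- estimate_exposure(led, pop, "total")
    setNames(e$exposure, e$group)
  }
  e1 <- est_one(1); e2 <- est_one(2)
  expect_identical(e1, est_one(1))
  expect_false(identical(e1, e2))
  # small-sample smoke check; the full calibration runs in acceptance
  draws <- t(vapply(1:20, est_one, e1))
  bias <- colMeans(draws)[["child_2_11"]] - m$truth$by_group[["child_2_11"]]
  sem <- stats::sd(draws[, "child_2_11"]) / sqrt(nrow(draws))
  expect_lt(abs(bias), 4 * sem + 1e-9)
})

test_that("nutrition sources respect tier structure and product mix leans unhealthy", {
  m <- generate_market(small_config(seed = 6L))
  expect_true(all(names(m$nutrition_sources) %in% nutrition_tiers()))
  prof <- lookup_nutrition(m$products$product_id, m$nutrition_sources)
  plab <- classify_products(prof, m$config$thresholds)
  frac_missing <- mean(prof$missing)
  expect_gt(frac_missing, 0.05); expect_lt(frac_missing, 0.6)
  present <- plab$label[plab$label != "unclassified"]
  expect_gt(mean(present == "unhealthy"), 0.5) # most products exceed
  # restaurant items resolve from the menu database most of the time
  rest <- m$products$coarse_category == "restaurants" & !prof$missing
  expect_gt(mean(prof$source_tier[rest] == "menu_flip_2016"), 0.5)
})
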