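test_that("compute_weights fills population/panel ratios per stratum", {
  s <- make_strata(child_pop = 1000, adol_pop = 0, child_n = 10)
  panel <- s$panel_sizes[rep(seq_len(nrow(s$panel_sizes)), s$panel_sizes$n)]
  panel[, member_id := sprintf("m%02d", .I)]
  w <- compute_weights(panel[, .(member_id, age_group, sex, hh_band)],
                       s$population)
  expect_equal(sum(w$weight), 1000) # weights recover the population total
  chk <- w[, .(n = .N, wt = unique(weight)), by = .(sex, hh_band)]
  expect_equal(chk$wt, 250 / chk$n)  # population_cell / panel_cell
})

test_that("panel equal to population gives unit weights; hand-sized strata check", {
  pop <- data.frame(age_group = c("child_2_11", "child_2_11"),
                    sex = c("f", "m"), hh_band = "hh_1_2",
                    population = c(600, 400))
  panel <- data.frame(
    member_id = sprintf("m%d", 1:10),
    age_group = "child_2_11", sex = rep(c("f", "m"), c(6, 4)),
    hh_band = "hh_1_2")
  w <- compute_weights(panel, pop)
  expect_equal(sort(unique(w$weight)), 100)   # 600/6 and 400/4
  expect_equal(sum(w$weight), 1000)

  pop1 <- data.frame(age_group = "child_2_11", sex = "f",
                     hh_band = "hh_1_2", population = 3)
  pan1 <- data.frame(member_id = c("a", "b", "c"),
                     age_group = "child_2_11", sex = "f", hh_band = "hh_1_2")
  expect_equal(compute_weights(pan1, pop1)$weight, c(1, 1, 1))
})

test_that("empty cells collapse upward; empty age groups error", {
  pop <- data.frame(age_group = "child_2_11", sex = c("f", "f"),
                    hh_band = c("hh_1_2", "hh_3plus"),
                    population = c(500, 500))
  panel <- data.frame(member_id = c("a", "b"), age_group = "child_2_11",
                      sex = "f", hh_band = "hh_1_2")
  # hh_3plus cell empty -> collapses into (child, f): each weight 1000/2
  w <- compute_weights(panel, pop)
  expect_equal(w$weight, c(500, 500))
  expect_equal(sum(w$weight), 1000)

  pop2 <- rbind(pop, data.frame(age_group = "adolescent_12_17", sex = "m",
                                hh_band = "hh_1_2", population = 100))
  expect_error(compute_weights(panel, pop2), "adolescent_12_17")
})

test_that("impressions require tuning at the airing start, half-open at the end", {
  airings <- data.table::data.table(station = "S", start = T0 + 3600,
                                    ad_id = "a")
  ads <- data.table::data.table(ad_id = "a", n_products = 1L)
  panel <- data.table::data.table(member_id = "m", age_group = "child_2_11",
                                  sex = "f", hh_band = "hh_1_2", weight = 1)
  all_day <- data.table::data.table(member_id = "m", station = "S",
                                    start = T0, end = T0 + 86400)
  expect_equal(nrow(count_impressions(airings, ads, all_day, panel)), 1L)

  ends_at <- data.table::data.table(member_id = "m", station = "S",
                                    start = T0, end = T0 + 3600)
  expect_equal(nrow(count_impressions(airings, ads, ends_at, panel)), 0L)
  starts_at <- data.table::data.table(member_id = "m", station = "S",
                                      start = T0 + 3600, end = T0 + 7200)
  expect_equal(nrow(count_impressions(airings, ads, starts_at, panel)), 1L)
})

test_that("ledger totals equal the double-loop oracle on a random fixture", {
  set.seed(99)
  stations <- c("S01", "S02", "S03")
  ads <- data.table::data.table(ad_id = sprintf("a%02d", 1:8),
                                n_products = sample(0:5, 8, TRUE))
  airings <- data.table::data.table(
    station = sample(stations, 40, TRUE),
    start = T0 + runif(40, 0, 86400),
    ad_id = sample(ads$ad_id, 40, TRUE))
  panel <- data.table::data.table(
    member_id = sprintf("m%02d", 1:6),
    age_group = sample(c("child_2_11", "adolescent_12_17"), 6, TRUE),
    sex = "f", hh_band = "hh_1_2", weight = runif(6, 1, 50))
  # non-overlapping random intervals per member
  viewing <- data.table::rbindlist(lapply(panel$member_id, function(m) {
    cuts <- sort(runif(6, 0, 86400))
    keep <- sample(c(TRUE, FALSE), 3, TRUE)
    data.table::data.table(member_id = m,
                           station = sample(stations, 3, TRUE),
                           start = T0 + cuts[c(1, 3, 5)],
                           end = T0 + cuts[c(2, 4, 6)])[keep]
  }))
  led <- count_impressions(airings, ads, viewing, panel)
  got <- tapply(led$member_weight * led$product_weight, led$age_group, sum)
  want <- oracle_impressions(airings, ads, viewing, panel)
  want <- want[want > 0]
  expect_equal(as.numeric(got[names(want)]), as.numeric(want))

  expect_error(count_impressions(airings[1][, ad_id := "ghost"], ads,
                                 viewing, panel), "ghost")
})

test_that("overlapping viewing intervals are rejected", {
  v <- data.table::data.table(member_id = "m", station = c("S1", "S2"),
                              start = T0 + c(0, 1800),
                              end = T0 + c(3600, 5400))
  expect_error(validate_viewing(v), "overlapping")
  expect_error(validate_viewing(data.table::data.table(
    member_id = "m", station = "S1", start = T0 + 10, end = T0 + 10)),
    "end > start")
})

test_that("exposure equals GRP/100 and respects the ExposureEstimate identities", {
  m <- tiny_market()
  led <- count_impressions(m$airings, m$ads, m$viewing, m$panel)
  est <- estimate_exposure(led, m$population_by_group, "total")
  expect_equal(est$grp, est$impressions / est$population * 100)
  expect_equal(est$exposure, est$grp / 100)
  expect_true(all(est$impressions >= 0))
  # impressions = population with 1-product ads -> exposure exactly 1
  one <- estimate_exposure(
    data.table::data.table(ad_id = "a", airing_id = 1L, station = "S",
                           at = T0, member_id = "m",
                           age_group = "child_2_11",
                           member_weight = 100, product_weight = 1L),
    c(child_2_11 = 100), "total")
  expect_equal(one$exposure, 1)
  expect_error(estimate_exposure(led, c(child_2_11 = 0)), "positive")
})

test_that("station slices partition total exposure; scale equivariance holds", {
  m <- tiny_market()
  led <- count_impressions(m$airings, m$ads, m$viewing, m$panel)
  tot <- estimate_exposure(led, m$population_by_group, "total")
  st <- estimate_exposure(led, m$population_by_group, "station")
  sums <- tapply(st$exposure, st$group, sum)
  expect_equal(as.numeric(sums[tot$group]), tot$exposure)

  scaled_panel <- data.table::copy(m$panel)[, weight := weight * 2]
  led2 <- count_impressions(m$airings, m$ads, m$viewing, scaled_panel)
  tot2 <- estimate_exposure(led2, m$population_by_group * 2, "total")
  expect_equal(tot2$exposure, tot$exposure)
  expect_equal(tot2$grp, tot$grp)
})

test_that("category slices are super-additive with multi-category ads", {
  m <- tiny_market()
  led <- count_impressions(m$airings, m$ads, m$viewing, m$panel)
  tot <- estimate_exposure(led, m$population_by_group, "total")
  cat_est <- estimate_exposure(led, m$population_by_group,
                               ad_category_slices(m$ad_products))
  sums <- tapply(cat_est$exposure, cat_est$group, sum)
  # ad1 spans snacks+restaurants (2 products, weight 1 in each row, 2 in
  # total); brand ad3 is in no category row
  for (g in tot$group) {
    led_g <- led[led$age_group == g, ]
    brand_part <- sum(led_g$member_weight[led_g$ad_id == "ad3"]) /
      m$population_by_group[[g]]
    expect_equal(sums[[g]], tot$exposure[tot$group == g] - brand_part)
  }
})

test_that("exposure is invariant to splitting viewing intervals", {
  m <- tiny_market()
  split_viewing <- data.table::rbindlist(lapply(
    seq_len(nrow(m$viewing)), function(i) {
      v <- m$viewing[i]
      mid <- v$start + as.numeric(v$end - v$start, units = "secs") / 2
      data.table::data.table(member_id = v$member_id, station = v$station,
                             start = c(v$start, mid), end = c(mid, v$end))
    }))
  led1 <- count_impressions(m$airings, m$ads, m$viewing, m$panel)
  led2 <- count_impressions(m$airings, m$ads, split_viewing, m$panel)
  e1 <- estimate_exposure(led1, m$population_by_group, "total")
  e2 <- estimate_exposure(led2, m$population_by_group, "total")
  expect_equal(e1$exposure, e2$exposure)
})
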