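library(data.table)

T0 <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")

# stratum tables split evenly over sex x hh cells
make_strata <- function(child_pop, adol_pop, other_pop = 0,
                        child_n = 0, adol_n = 0, other_n = 0) {
  cells <- CJ(age_group = c("child_2_11", "adolescent_12_17", "other"),
              sex = c("f", "m"), hh_band = c("hh_1_2", "hh_3plus"))
  pop_tot <- c(child_2_11 = child_pop, adolescent_12_17 = adol_pop,
               other = other_pop)
  pan_tot <- c(child_2_11 = child_n, adolescent_12_17 = adol_n,
               other = other_n)
  pop <- copy(cells)[, population := pop_tot[age_group] / 4]
  pan <- copy(cells)[, n := {
    tot <- pan_tot[age_group[1]]
    tot %/% 4 + as.integer(seq_len(.N) <= tot %% 4)
  }, by = age_group]
  pop <- pop[population > 0]
  pan <- pan[n > 0]
  list(population = pop, panel_sizes = pan)
}

# hand-built two-station micro market used across modules
tiny_market <- function() {
  products <- data.table(
    product_id = c("p1", "p2", "p3", "p4"),
    name = paste("prod", 1:4),
    fine_category = c("snacks_01", "snacks_02", "restaurants_01", "dairy_01"),
    coarse_category = c("snacks", "snacks", "restaurants", "dairy"))
  ads <- data.table(
    ad_id = c("ad1", "ad2", "ad3"),
    content_key = c("k1", "k2", "k3"),
    language = "en", duration = c(15L, 30L, 15L),
    n_products = c(2L, 1L, 0L), is_brand = c(FALSE, FALSE, TRUE))
  ad_products <- data.table(
    ad_id = c("ad1", "ad1", "ad2"),
    product_id = c("p1", "p3", "p4"),
    fine_category = c("snacks_01", "restaurants_01", "dairy_01"))
  airings <- data.table(
    station = c("S01", "S01", "S02", "S02"),
    start = T0 + c(3600, 7200, 3600, 50000),
    ad_id = c("ad1", "ad2", "ad1", "ad3"))
  panel <- data.table(
    member_id = c("m1", "m2", "m3"),
    age_group = c("child_2_11", "child_2_11", "adolescent_12_17"),
    sex = "f", hh_band = "hh_1_2",
    weight = c(50, 50, 80))
  viewing <- data.table(
    member_id = c("m1", "m1", "m2", "m3"),
    station = c("S01", "S02", "S01", "S02"),
    start = T0 + c(0, 40000, 7000, 0),
    end = T0 + c(10000, 60000, 7300, 86400))
  list(products = products, ads = ads, ad_products = ad_products,
       airings = airings, panel = panel, viewing = viewing,
       population_by_group = c(child_2_11 = 100, adolescent_12_17 = 80))
}

# pure double-loop impression oracle: weighted impressions by group,
# intentionally naive and independent of the package's join
oracle_impressions <- function(airings, ads, viewing, panel) {
  imp <- c()
  for (g in unique(panel$age_group)) imp[g] <- 0
  for (i in seq_len(nrow(airings))) {
    ad <- as.list(ads[ads$ad_id == airings$ad_id[i], ])
    pwt <- min(max(ad$n_products, 1), 3)
    for (j in seq_len(nrow(panel))) {
      m <- panel$member_id[j]
      tuned <- FALSE
      for (k in seq_len(nrow(viewing))) {
        if (viewing$member_id[k] == m &&
            viewing$station[k] == airings$station[i] &&
            viewing$start[k] <= airings$start[i] &&
            airings$start[i] < viewing$end[k]) tuned <- TRUE
      }
      if (tuned)
        imp[panel$age_group[j]] <- imp[panel$age_group[j]] +
          panel$weight[j] * pwt
    }
  }
  imp
}

# naive per-category weighted-frequency recount
oracle_category_freq <- function(airings, ads, ad_products, map) {
  out <- c()
  for (cat in unique(map$coarse_category)) out[cat] <- 0
  for (a in unique(ads$ad_id)) {
    n_air <- sum(airings$ad_id == a)
    if (n_air == 0) next
    prods <- ad_products[ad_products$ad_id == a, ]
    if (nrow(prods) == 0) next
    coarse <- map$coarse_category[match(prods$fine_category,
                                        map$fine_category)]
    for (cat in unique(coarse))
      out[cat] <- out[cat] + min(sum(coarse == cat), 3) * n_air
  }
  out[out > 0]
}

# random nutrient profiles for property tests
random_profiles <- function(n, cfg, seed) {
  set.seed(seed)
  data.table(
    product_id = sprintf("rp%03d", seq_len(n)),
    basis = cfg$basis,
    saturated_fat_g = runif(n, 0, 5),
    sugars_g = runif(n, 0, 12),
    sodium_mg = runif(n, 0, 500),
    added_fat = runif(n) < 0.5,
    added_sugar = runif(n) < 0.5,
    added_sodium = runif(n) < 0.5,
    missing = FALSE)
}

# wide coding table from a logical matrix (rows = ads)
make_codings <- function(mat, coder, ad_ids = sprintf("a%02d", seq_len(nrow(mat)))) {
  cd <- data.table(ad_id = ad_ids, coder_id = coder)
  for (j in seq_len(ncol(mat))) cd[, (colnames(mat)[j]) := mat[, j]]
  cd
}
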