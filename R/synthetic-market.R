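#' Generate a synthetic advertising market
#'
#' Builds a complete, internally consistent market from a
#' [market_config()]: stations, a product pool with nutrition spread over
#' provenance tiers, unique ads (some multi-product, some brand-only),
#' technique codings, a full-year-style airing schedule, a synthetic
#' population with per-person viewing sessions, a stratified people-meter
#' panel drawn from that population with post-stratification weights, and
#' exhaustive ground-truth exposure computed over the entire population by
#' [compute_ground_truth()].
#'
#' Deterministic given `config$seed`: every stage draws from its own named
#' substream, so regeneration is bit-identical and stages are independently
#' reproducible.
#'
#' @param config a validated [market_config()].
#' @return List of class `ad_market`: `config`, `stations`, `products`,
#'   `nutrition_sources` (named list of tier tables), `ads`, `ad_products`,
#'   `codings` (wide technique truth), `airings`, `persons`,
#'   `population_viewing`, `panel` (weighted), `viewing` (panel subset),
#'   `truth` (see [compute_ground_truth()]).
#' @export
generate_market <- function(config = market_config()) {
  validate_market_config(config)
  seed <- config$seed
  origin <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")

  stations <- sprintf("S%02d", seq_len(config$n_stations))
  pop_tab <- config$population_by_stratum
  ages <- unique(pop_tab$age_group)

  # station popularity and per-age-group preference weights
  prefs <- with_substream(seed, "stations", {
    popularity <- rgamma(config$n_stations, shape = 1.5)
    popularity <- popularity / sum(popularity)
    pr <- lapply(ages, function(a) {
      conc <- config$viewing_model_params[[a]]$station_concentration
      w <- popularity * rgamma(config$n_stations, shape = conc)
      w / sum(w)
    })
    names(pr) <- ages
    list(popularity = popularity, by_age = pr)
  })

  products <- with_substream(seed, "products", {
    n_pool <- max(50L, ceiling(config$n_unique_ads * 0.8))
    mix <- config$category_mix
    coarse <- sample(names(mix), n_pool, replace = TRUE, prob = mix)
    map <- default_category_map()
    fine <- vapply(coarse, function(cc) {
      cand <- map$fine_category[map$coarse_category == cc]
      cand[sample.int(length(cand), 1L)]
    }, "")
    data.table(product_id = sprintf("P%05d", seq_len(n_pool)),
               name = sprintf("product %05d", seq_len(n_pool)),
               fine_category = unname(fine), coarse_category = coarse)
  })

  nutrition_sources <- with_substream(seed, "nutrition",
    generate_nutrition(products, config))

  adm <- with_substream(seed, "ads", {
    n_ads <- config$n_unique_ads
    is_brand <- runif(n_ads) < config$p_brand_ad
    dist <- config$products_per_ad_dist
    k <- as.integer(names(dist))[
      sample.int(length(dist), n_ads, replace = TRUE, prob = dist)]
    k[is_brand] <- 0L
    primary <- sample(names(config$category_mix), n_ads, replace = TRUE,
                      prob = config$category_mix)
    by_cat <- split(products$product_id, products$coarse_category)
    links <- vector("list", n_ads)
    for (i in seq_len(n_ads)) {
      if (k[i] == 0L) next
      pool <- by_cat[[primary[i]]]
      pick <- character(k[i])
      for (j in seq_len(k[i])) {
        use_primary <- length(pool) > 0L && runif(1) < 0.85
        src <- if (use_primary) pool else products$product_id
        src <- setdiff(src, pick)
        if (!length(src)) src <- setdiff(products$product_id, pick)
        pick[j] <- src[sample.int(length(src), 1L)]
      }
      links[[i]] <- pick
    }
    ads <- data.table(
      ad_id = sprintf("A%05d", seq_len(n_ads)),
      content_key = sprintf("ck%05d", seq_len(n_ads)),
      language = sample(c("en", "fr"), n_ads, replace = TRUE,
                        prob = c(0.9, 0.1)),
      duration = sample(c(15L, 30L, 60L), n_ads, replace = TRUE,
                        prob = c(0.5, 0.4, 0.1)),
      n_products = k, is_brand = is_brand)
    ap <- data.table(ad_id = rep(ads$ad_id, lengths(links)),
                     product_id = unlist(links))
    if (nrow(ap))
      ap <- merge(ap, products[, .(product_id, fine_category)],
                  by = "product_id", sort = FALSE)[, .(ad_id, product_id,
                                                       fine_category)]
    list(ads = ads, ad_products = ap)
  })
  ads <- adm$ads
  ad_products <- adm$ad_products

  codings <- with_substream(seed, "codings", {
    prev <- technique_prevalence()
    cd <- data.table(ad_id = ads$ad_id)
    for (tc in technique_codebook()$code)
      cd[, (tc) := runif(nrow(ads)) < prev[[tc]]]
    cd
  })

  airings <- with_substream(seed, "airings", {
    n_air <- as.integer(round(config$n_stations * config$n_days *
                                config$airings_per_station_day))
    propensity <- rgamma(nrow(ads), shape = 0.8)
    data.table(
      station = sample(stations, n_air, replace = TRUE,
                       prob = prefs$popularity),
      start = origin + sample.int(config$n_days, n_air, replace = TRUE) *
        86400 - 86400 + runif(n_air, 0, 86400),
      ad_id = sample(ads$ad_id, n_air, replace = TRUE,
                     prob = propensity / sum(propensity))
    )[order(start)]
  })

  persons <- pop_tab[rep(seq_len(nrow(pop_tab)), pop_tab$population)]
  persons[, person_id := sprintf("p%06d", .I)]
  persons <- persons[, .(person_id, age_group, sex, hh_band)]

  population_viewing <- with_substream(seed, "viewing",
    generate_viewing(persons, stations, prefs$by_age, config, origin))

  panel_members <- with_substream(seed, "panel", {
    pan <- config$panel_size_by_stratum
    idx <- unlist(lapply(seq_len(nrow(pan)), function(i) {
      cand <- which(persons$age_group == pan$age_group[i] &
                      persons$sex == pan$sex[i] &
                      persons$hh_band == pan$hh_band[i])
      cand[sample.int(length(cand), pan$n[i])]
    }))
    persons[idx]
  })
  panel <- compute_weights(
    panel_members[, .(member_id = person_id, age_group, sex, hh_band)],
    pop_tab)
  viewing <- population_viewing[member_id %in% panel$member_id]

  truth <- compute_ground_truth(airings, population_viewing, ads, persons)

  structure(list(config = config, stations = stations, products = products,
                 nutrition_sources = nutrition_sources, ads = ads,
                 ad_products = ad_products, codings = codings,
                 airings = airings, persons = persons,
                 population_viewing = population_viewing,
                 panel = panel, viewing = viewing, truth = truth),
            class = "ad_market")
}

# nutrition tables per provenance tier; amounts generated relative to the
# threshold config so p_exceeds_threshold is exact by construction
generate_nutrition <- function(products, config) {
  th <- config$thresholds$thresholds
  n <- nrow(products)
  missing <- runif(n) < config$p_missing_nutrition
  exceeds <- runif(n) < config$p_exceeds_threshold
  nuts <- names(th)
  amounts <- matrix(0, n, length(nuts), dimnames = list(NULL, nuts))
  flags <- matrix(FALSE, n, length(nuts))
  for (j in seq_along(nuts)) {
    lim <- as.numeric(th[[j]]$limit)
    amounts[, j] <- runif(n, 0, 0.9 * lim)
    flags[, j] <- runif(n) < 0.6
  }
  # exceeding products: one random gated nutrient pushed above its limit
  over <- which(exceeds)
  pick <- sample.int(length(nuts), length(over), replace = TRUE)
  for (i in seq_along(over)) {
    j <- pick[i]
    amounts[over[i], j] <- as.numeric(th[[j]]$limit) * runif(1, 1.2, 4)
    flags[over[i], j] <- TRUE
  }
  # non-exceeding products must not exceed through any *flagged* nutrient:
  # amounts already < limit, nothing to do (strict rule)
  tab <- data.table(product_id = products$product_id,
                    basis = config$thresholds$basis)
  for (j in seq_along(nuts)) tab[, (nuts[j]) := amounts[, j]]
  flag_names <- vapply(th, function(t) t$added_flag, "")
  for (j in seq_along(nuts)) tab[, (flag_names[j]) := flags[, j]]

  present <- tab[!missing]
  pres_products <- products[!missing]
  tier <- character(nrow(present))
  is_rest <- pres_products$coarse_category == "restaurants"
  lower <- c("company_ca_site", "nft_online", "company_us_site",
             "cnf_substitute")
  r <- runif(nrow(present))
  tier[is_rest] <- ifelse(r[is_rest] < 0.9, "menu_flip_2016",
                          sample(lower, sum(is_rest), replace = TRUE))
  tier[!is_rest] <- ifelse(r[!is_rest] < 0.85, "flip_2017",
                           sample(lower, sum(!is_rest), replace = TRUE))
  split(present, tier)[intersect(nutrition_tiers(), unique(tier))]
}

# per-person daily viewing sessions: Poisson session counts, uniform
# starts, exponential durations truncated at the next session and at
# midnight; station drawn from the person's age-group preferences
generate_viewing <- function(persons, stations, prefs_by_age, config,
                             origin) {
  vp <- config$viewing_model_params
  lambda <- vapply(persons$age_group,
                   function(a) vp[[a]]$sessions_per_day, 0)
  mean_sess <- vapply(persons$age_group, function(a)
    vp[[a]]$mean_daily_minutes * 60 / vp[[a]]$sessions_per_day, 0)
  n_p <- nrow(persons)
  n_days <- config$n_days
  counts <- rpois(n_p * n_days, rep(lambda, times = n_days))
  m <- sum(counts)
  if (m == 0L)
    return(data.table(member_id = character(0), station = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC")))
  pid_idx <- rep(rep(seq_len(n_p), times = n_days), counts)
  day <- rep(rep(seq_len(n_days) - 1L, each = n_p), counts)
  s <- runif(m, 0, 86400)
  dur <- rexp(m, rate = 1 / mean_sess[pid_idx])
  dt <- data.table(pid = pid_idx, day = day, s = s, dur = dur,
                   age = persons$age_group[pid_idx])
  setorder(dt, pid, day, s)
  dt[, e := pmin(s + dur, data.table::shift(s, -1L, fill = 86400)),
     by = .(pid, day)]
  # station by age-group preference
  dt[, station := {
    pr <- prefs_by_age[[age[1]]]
    stations[sample.int(length(stations), .N, replace = TRUE, prob = pr)]
  }, by = age]
  dt <- dt[e > s]
  data.table(member_id = persons$person_id[dt$pid],
             station = dt$station,
             start = origin + dt$day * 86400 + dt$s,
             end = origin + dt$day * 86400 + dt$e)
}

#' Exhaustive ground-truth exposure over a full population
#'
#' Counts, for every person in the synthetic population and every airing,
#' whether the person's TV was tuned to the airing's station at its start
#' instant (half-open intervals), weights by the ad's capped product count,
#' and divides by the group population. This is the brute-force oracle the
#' panel-based estimator is validated against; it shares no code with
#' [count_impressions()]'s join (station/day-bucketed linear scans in base
#' R).
#'
#' @param airings data.frame `station`, `start`, `ad_id`.
#' @param viewing full-population viewing intervals (`member_id`,
#'   `station`, `start`, `end`).
#' @param ads data.frame `ad_id`, `n_products`.
#' @param persons data.frame `person_id`, `age_group` covering the whole
#'   population.
#' @return List: `by_group` (named exposure, ads/person/period),
#'   `by_group_station` (`data.table` group, station, exposure),
#'   `population_by_group` (named counts).
#' @export
compute_ground_truth <- function(airings, viewing, ads, persons) {
  a <- as.data.frame(airings)
  v <- as.data.frame(viewing)
  ads <- as.data.frame(ads)
  persons <- as.data.frame(persons)
  pw_of_ad <- setNames(capped_product_weight(ads$n_products), ads$ad_id)
  if (anyNA(pw_of_ad[a$ad_id])) stop("airings reference unknown ads")
  pw <- unname(pw_of_ad[a$ad_id])

  groups <- sort(unique(persons$age_group))
  g_idx <- setNames(match(persons$age_group, groups), persons$person_id)
  pop <- as.numeric(table(factor(persons$age_group, levels = groups)))
  names(pop) <- groups

  at <- as.numeric(a$start)
  vs <- as.numeric(v$start)
  ve <- as.numeric(v$end)
  gv <- unname(g_idx[as.character(v$member_id)])
  if (anyNA(gv)) stop("viewing references persons missing from the population")

  # bucket intervals by (station, day); an interval joins every day bucket
  # it overlaps so airings near midnight still see it
  day0 <- min(c(vs, at))
  d_from <- floor((vs - day0) / 86400)
  d_to <- floor((ve - day0 - 1e-9) / 86400)
  reps <- pmax(d_to - d_from + 1L, 1L)
  row <- rep(seq_along(vs), reps)
  dday <- unlist(lapply(seq_along(vs),
                        function(i) seq(d_from[i], d_to[i])), use.names = FALSE)
  bkey <- paste(v$station[row], dday)
  buckets <- split(row, bkey)

  a_key <- paste(a$station, floor((at - day0) / 86400))
  ng <- length(groups)
  imp_total <- numeric(ng)
  st_list <- unique(a$station)
  imp_station <- matrix(0, ng, length(st_list),
                        dimnames = list(groups, st_list))
  for (i in seq_along(at)) {
    idx <- buckets[[a_key[i]]]
    if (is.null(idx)) next
    sel <- vs[idx] <= at[i] & at[i] < ve[idx]
    if (!any(sel)) next
    cnt <- tabulate(gv[idx][sel], nbins = ng)
    imp_total <- imp_total + pw[i] * cnt
    imp_station[, a$station[i]] <- imp_station[, a$station[i]] + pw[i] * cnt
  }
  by_group <- imp_total / pop
  names(by_group) <- groups
  by_station <- data.table(
    group = rep(groups, times = length(st_list)),
    station = rep(st_list, each = ng),
    exposure = as.vector(imp_station / pop))
  list(by_group = by_group, by_group_station = by_station[order(group, station)],
       population_by_group = pop)
}

#' Redraw the people-meter panel from a generated market
#'
#' Samples a fresh stratified panel (per-stratum sizes from the market's
#' config) out of the synthetic population, recomputes post-stratification
#' weights, and returns the panel with its viewing subset. Used to study
#' the sampling distribution of the exposure estimator around the market's
#' fixed ground truth.
#'
#' @param market an `ad_market` from [generate_market()].
#' @param seed seed for the panel draw.
#' @return List: `panel` (weighted), `viewing`.
#' @export
resample_panel <- function(market, seed) {
  persons <- market$persons
  pan <- market$config$panel_size_by_stratum
  idx <- with_substream(seed, "panel_resample",
    unlist(lapply(seq_len(nrow(pan)), function(i) {
      cand <- which(persons$age_group == pan$age_group[i] &
                      persons$sex == pan$sex[i] &
                      persons$hh_band == pan$hh_band[i])
      cand[sample.int(length(cand), pan$n[i])]
    })))
  members <- persons[idx]
  panel <- compute_weights(
    members[, .(member_id = person_id, age_group, sex, hh_band)],
    market$config$population_by_stratum)
  list(panel = panel,
       viewing = market$population_viewing[member_id %in% panel$member_id])
}

#' Group population totals of a market
#'
#' @param market an `ad_market`.
#' @return Named numeric: population by age group.
#' @export
population_by_group <- function(market) {
  market$truth$population_by_group
}
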