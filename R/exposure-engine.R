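#' Compose a stratum key
#'
#' Strata are age group x sex x household-size band, the demographic cells
#' the viewing panel is weighted on.
#'
#' @param age_group,sex,hh_band character vectors (recycled).
#' @return Character vector of `age|sex|hh` keys.
#' @export
stratum_key <- function(age_group, sex, hh_band) {
  paste(age_group, sex, hh_band, sep = "|")
}

#' Post-stratification weights for a viewing panel
#'
#' Fills each panel member's weight with the number of market persons they
#' represent: population of their demographic cell divided by the number of
#' panelists in that cell. Cells are age group x sex x household-size band.
#' If a cell has population but no panelists, the partition is coarsened
#' before weighting: all household-size cells of that age x sex block
#' collapse into one cell, and if a whole age x sex block is unrepresented
#' the age group collapses to a single cell. An age group with population
#' but no panelists at all is an error.
#'
#' Weights over the final partition always sum to the total population.
#'
#' @param panel data.frame with `member_id`, `age_group`, `sex`, `hh_band`.
#' @param population_by_stratum data.frame with `age_group`, `sex`,
#'   `hh_band`, `population`.
#' @return `data.table`: the panel with a `weight` column filled.
#' @examples
#' panel <- data.frame(member_id = c("m1", "m2"),
#'                     age_group = "child_2_11", sex = "f", hh_band = "small")
#' pop <- data.frame(age_group = "child_2_11", sex = "f", hh_band = "small",
#'                   population = 1000)
#' compute_weights(panel, pop)$weight  # 500 500
#' @export
compute_weights <- function(panel, population_by_stratum) {
  panel <- copy(as.data.table(panel))
  pop <- copy(as.data.table(population_by_stratum))
  req <- c("age_group", "sex", "hh_band")
  if (!all(c(req, "population") %in% names(pop)))
    stop("population_by_stratum needs columns age_group, sex, hh_band, population")
  if (!all(c("member_id", req) %in% names(panel)))
    stop("panel needs columns member_id, age_group, sex, hh_band")
  pop <- pop[population > 0]

  # choose the finest partition level representable by the panel
  cell_of <- function(df, lvl) {
    switch(lvl,
           hs  = stratum_key(df$age_group, df$sex, df$hh_band),
           s   = stratum_key(df$age_group, df$sex, "*"),
           age = stratum_key(df$age_group, "*", "*"))
  }
  panel_lvl <- function(lvl) unique(cell_of(panel, lvl))

  pop[, cell := cell_of(pop, "hs")]
  # age x sex blocks where every populated hh cell has panelists keep hh detail
  blk <- pop[, .(ok = all(cell %in% panel_lvl("hs"))),
             by = .(age_group, sex)]
  pop <- merge(pop, blk, by = c("age_group", "sex"))
  pop[ok == FALSE, cell := cell_of(.SD, "s")]
  # collapsed blocks with no panelists at sex level fall back to age level
  pop[!(cell %in% c(panel_lvl("hs"), panel_lvl("s"))),
      cell := cell_of(.SD, "age")]
  empty <- setdiff(pop$cell,
                   c(panel_lvl("hs"), panel_lvl("s"), panel_lvl("age")))
  if (length(empty))
    stop("strata with population but no panelists after collapsing: ",
         paste(unique(empty), collapse = ", "))

  cell_pop <- pop[, .(population = sum(population)), by = cell]
  # a member belongs to the finest cell that survived in the partition
  panel[, cell := stratum_key(age_group, sex, hh_band)]
  panel[!(cell %in% cell_pop$cell), cell := stratum_key(age_group, sex, "*")]
  panel[!(cell %in% cell_pop$cell), cell := stratum_key(age_group, "*", "*")]
  n_cell <- panel[, .(n = .N), by = cell]
  w <- merge(cell_pop, n_cell, by = "cell")
  panel <- merge(panel, w[, .(cell, weight = population / n)],
                 by = "cell", all.x = TRUE)
  panel[is.na(weight), weight := 0] # panelist cell absent from population
  panel[, cell := NULL]
  setcolorder(panel, c("member_id", "age_group", "sex", "hh_band", "weight"))
  panel[]
}

#' Validate viewing intervals
#'
#' Checks `end > start` and that no member is recorded on two stations at
#' overlapping times (the people meter observes one tuned set).
#'
#' @param viewing data.frame with `member_id`, `station`, `start`, `end`.
#' @return The intervals, invisibly, as a `data.table`.
#' @export
validate_viewing <- function(viewing) {
  v <- as.data.table(viewing)
  if (any(v$end <= v$start))
    stop("viewing intervals must satisfy end > start")
  setorder(v, member_id, start)
  ov <- v[, .(bad = .N > 1L && any(head(end, -1L) > start[-1L])),
          by = member_id]
  if (any(ov$bad))
    stop("overlapping viewing intervals for members: ",
         paste(head(ov$member_id[ov$bad], 5L), collapse = ", "))
  invisible(v)
}

#' Impression ledger from airings and viewing intervals
#'
#' A panel member registers an impression for an airing iff they have a
#' viewing interval on the airing's station that covers the airing's start
#' instant. Intervals are half-open `[start, end)`: an airing at the exact
#' end of an interval is not an impression. Each ledger row carries the ad's
#' capped product weight and the member's post-stratification weight.
#'
#' @param airings data.frame with `station`, `start`, `ad_id`.
#' @param ads data.frame with `ad_id`, `n_products`.
#' @param viewing data.frame with `member_id`, `station`, `start`, `end`.
#' @param panel weighted panel from [compute_weights()].
#' @return `data.table` ledger: `airing_id`, `ad_id`, `station`, `at`,
#'   `member_id`, `age_group`, `member_weight`, `product_weight`.
#' @export
count_impressions <- function(airings, ads, viewing, panel) {
  a <- as.data.table(airings)
  ads <- as.data.table(ads)
  panel <- as.data.table(panel)
  unknown <- setdiff(a$ad_id, ads$ad_id)
  if (length(unknown))
    stop("airings reference unknown ads: ",
         paste(head(unknown, 5L), collapse = ", "))
  v <- copy(validate_viewing(viewing))
  a <- copy(a)[, airing_id := .I]
  setnames(v, c("start", "end"), c("v_start", "v_end"))
  led <- v[a, on = .(station, v_start <= start, v_end > start),
           .(airing_id = i.airing_id, ad_id = i.ad_id, station,
             at = i.start, member_id = x.member_id),
           nomatch = NULL, allow.cartesian = TRUE]
  led <- merge(led, ads[, .(ad_id, product_weight = capped_product_weight(n_products))],
               by = "ad_id")
  led <- merge(led,
               panel[, .(member_id, age_group, member_weight = weight)],
               by = "member_id")
  setcolorder(led, c("airing_id", "ad_id", "station", "at", "member_id",
                     "age_group", "member_weight", "product_weight"))
  setorder(led, airing_id, member_id)
  led[]
}

#' GRP and per-capita exposure estimates by group and slice
#'
#' Aggregates an impression ledger into exposure estimates. For each age
#' group and slice, `impressions` is the member-weight x product-weight sum
#' of qualifying ledger rows, `grp = impressions / population * 100`, and
#' `exposure = grp / 100` (average ads viewed per person over the period).
#'
#' Slicing:
#' \describe{
#'   \item{`"total"`}{one row per group; each ad counted once at its overall
#'     capped product weight.}
#'   \item{`"station"`}{rows partition the total (stations are disjoint).}
#'   \item{a slice table}{pass a data.frame `ad_id`, `slice`, `weight` (e.g.
#'     from [ad_category_slices()], [ad_technique_slices()],
#'     [ad_npm_slices()]); `weight` replaces the ledger's product weight, so
#'     multi-category ads may make category rows super-additive.}
#' }
#'
#' @param ledger impression ledger from [count_impressions()].
#' @param population_by_group named numeric vector of group population
#'   totals (all > 0).
#' @param slice_by `"total"`, `"station"`, or a slice table (see above).
#' @return `data.table` with `group`, `slice`, `impressions`, `population`,
#'   `grp`, `exposure`; every group appears in every slice (0 when unseen).
#' @export
estimate_exposure <- function(ledger, population_by_group, slice_by = "total") {
  led <- as.data.table(ledger)
  if (is.null(names(population_by_group)) || any(population_by_group <= 0))
    stop("population_by_group must be a named vector of positive totals")
  groups <- names(population_by_group)

  if (is.character(slice_by) && length(slice_by) == 1L) {
    imp <- switch(slice_by,
      total   = led[, .(slice = "total",
                        impressions = sum(member_weight * product_weight)),
                    by = .(group = age_group)],
      station = led[, .(impressions = sum(member_weight * product_weight)),
                    by = .(group = age_group, slice = station)],
      stop("slice_by must be 'total', 'station', or a slice table"))
    slices <- if (slice_by == "total") "total" else sort(unique(led$station))
  } else {
    st <- as.data.table(slice_by)
    if (!all(c("ad_id", "slice", "weight") %in% names(st)))
      stop("slice table needs columns ad_id, slice, weight")
    x <- merge(led[, .(ad_id, age_group, member_weight)], st,
               by = "ad_id", allow.cartesian = TRUE)
    imp <- x[, .(impressions = sum(member_weight * weight)),
             by = .(group = age_group, slice)]
    slices <- sort(unique(st$slice))
  }

  grid <- CJ(group = groups, slice = slices)
  out <- merge(grid, imp, by = c("group", "slice"), all.x = TRUE)
  out[is.na(impressions), impressions := 0]
  out[, population := population_by_group[group]]
  out[, grp := impressions / population * 100]
  out[, exposure := grp / 100]
  setorder(out, group, slice)
  out[]
}

#' Per-ad coarse-category slice table
#'
#' One row per (ad, coarse category) its products fall in, weighted by the
#' per-category product count capped at 3. Brand ads contribute no rows.
#'
#' @param ad_products data.frame with `ad_id`, `fine_category`.
#' @param map category map.
#' @return `data.table` `ad_id`, `slice`, `weight` for [estimate_exposure()].
#' @export
ad_category_slices <- function(ad_products, map = default_category_map()) {
  ap <- copy(as.data.table(ad_products))
  ap[, coarse_category := map_fine_to_coarse(fine_category, map)]
  # distinct products only: a duplicated product row adds no weight
  ap[, .(weight = pmin(uniqueN(product_id), 3L)),
     by = .(ad_id, slice = coarse_category)]
}

#' Per-ad marketing-technique slice table
#'
#' One row per (ad, technique present in the ad), at the ad's overall capped
#' product weight: technique exposure counts the same food-product units as
#' the total, restricted to ads featuring the technique. Techniques are
#' per-ad, so duplicating a product changes nothing here.
#'
#' @param codings wide codings (`ad_id` + one logical column per technique),
#'   e.g. consensus output of [resolve_consensus()].
#' @param ads data.frame with `ad_id`, `n_products`.
#' @return `data.table` `ad_id`, `slice`, `weight`.
#' @export
ad_technique_slices <- function(codings, ads) {
  cd <- as.data.table(codings)
  ads <- as.data.table(ads)
  tech_cols <- setdiff(names(cd), c("ad_id", "coder_id", "round"))
  long <- melt(cd[, c("ad_id", tech_cols), with = FALSE], id.vars = "ad_id",
               variable.name = "slice", value.name = "present",
               variable.factor = FALSE)
  long <- long[present == TRUE]
  long <- merge(long, ads[, .(ad_id, weight = capped_product_weight(n_products))],
                by = "ad_id")
  long[, .(ad_id, slice, weight)]
}

#' Per-ad healthfulness slice table
#'
#' Rows only for classified ads (healthy/unhealthy), at the overall capped
#' product weight; unclassified ads (brand ads, missing nutrition) drop out
#' of the denominator.
#'
#' @param ad_labels data.frame with `ad_id`, `label` from [classify_ads()].
#' @param ads data.frame with `ad_id`, `n_products`.
#' @return `data.table` `ad_id`, `slice`, `weight`.
#' @export
ad_npm_slices <- function(ad_labels, ads) {
  lab <- as.data.table(ad_labels)
  ads <- as.data.table(ads)
  lab <- lab[label %in% c("healthy", "unhealthy")]
  lab <- merge(lab, ads[, .(ad_id, weight = capped_product_weight(n_products))],
               by = "ad_id")
  lab[, .(ad_id, slice = label, weight)]
}
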