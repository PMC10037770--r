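#' Capped product weight of an advertisement
#'
#' Advertisements are frequency-weighted by the number of featured products,
#' capped at 3; a brand advertisement with no identifiable product counts as
#' one creative unit.
#'
#' @param n_products integer vector of product counts (0 = brand ad).
#' @return Integer vector in 1..3.
#' @export
capped_product_weight <- function(n_products) {
  if (any(n_products < 0, na.rm = TRUE)) stop("n_products must be >= 0")
  as.integer(pmin(pmax(n_products, 1L), 3L))
}

#' Product-weighted advertisement frequency
#'
#' The weighted frequency of an advertisement is its number of featured
#' products multiplied by the number of times it aired, with the product
#' count capped at 3. An ad with 2 products aired 500 times has weighted
#' frequency 1000; with 4 products (capped to 3) it is 1500. Brand ads
#' (0 products) carry weight 1 per airing.
#'
#' @param n_products integer vector, products featured per ad (>= 0).
#' @param n_airings integer vector, number of broadcasts (>= 0).
#' @return Numeric vector of weighted frequencies.
#' @examples
#' weighted_frequency(2, 500)  # 1000
#' weighted_frequency(4, 500)  # 1500, cap at 3 products
#' @export
weighted_frequency <- function(n_products, n_airings) {
  if (any(n_airings < 0, na.rm = TRUE)) stop("n_airings must be >= 0")
  capped_product_weight(n_products) * as.numeric(n_airings)
}

#' Deduplicate unique advertisements
#'
#' Two records describe the same unique ad iff they agree on all three
#' identity dimensions: creative content (`content_key`), `language` and
#' `duration`. The first occurrence of each identity triple is kept, so the
#' operation is stable and idempotent.
#'
#' @param raw_ads data.frame of candidate records with at least
#'   `content_key`, `language`, `duration` populated.
#' @return `data.table` with one representative row per identity triple, in
#'   first-occurrence order; the number of distinct ads is `nrow()` of the
#'   result and is also attached as attribute `n_unique`.
#' @export
dedupe_unique_ads <- function(raw_ads) {
  x <- as.data.table(raw_ads)
  req <- c("content_key", "language", "duration")
  if (!all(req %in% names(x)))
    stop("ad records must have identity fields: ", paste(req, collapse = ", "))
  bad <- which(is.na(x$content_key) | is.na(x$language) | is.na(x$duration))
  if (length(bad))
    stop("records with missing identity fields at indices: ",
         paste(head(bad, 10L), collapse = ", "))
  out <- x[!duplicated(x, by = req)]
  setattr(out, "n_unique", nrow(out))
  out
}

#' Weighted advertisement frequency by coarse food category
#'
#' Tabulates product-weighted advertising frequency per coarse category,
#' with each ad contributing its per-category product count (capped at 3)
#' to every category its products fall in, while the grand total counts each
#' ad once at its overall capped weight. Category rows of a market with
#' multi-category ads therefore sum to more than the total row; percentages
#' are taken against the ad-level total. Brand ads enter the total at weight
#' 1 per airing but appear in no category row.
#'
#' @param airings data.frame of occurrences with columns `station`, `start`,
#'   `ad_id`.
#' @param ads data.frame of unique ads with `ad_id` and `n_products`.
#' @param ad_products data.frame linking `ad_id` to `product_id` and
#'   `fine_category`.
#' @param map category map (see [default_category_map()]).
#' @return `data.table` with one row per coarse category plus a `total` row:
#'   columns `category`, `weighted_freq`, `pct` (share of the ad-level
#'   total, in percent).
#' @export
frequency_table <- function(airings, ads, ad_products,
                            map = default_category_map()) {
  airings <- as.data.table(airings)
  ads <- as.data.table(ads)
  ap <- copy(as.data.table(ad_products))
  unknown <- setdiff(airings$ad_id, ads$ad_id)
  if (length(unknown))
    stop("airings reference unknown ads: ",
         paste(head(unknown, 5L), collapse = ", "))
  n_air <- airings[, .(airings = .N), by = ad_id]

  # grand total: each ad once, overall capped weight (brand ads weight 1)
  tot <- merge(n_air, ads[, .(ad_id, n_products)], by = "ad_id")
  total_wf <- sum(weighted_frequency(tot$n_products, tot$airings))

  # category rows: per-ad per-category product counts, capped at 3 per row
  ap[, coarse_category := map_fine_to_coarse(fine_category, map)]
  per_cat <- ap[, .(cat_weight = pmin(uniqueN(product_id), 3L)),
                by = .(ad_id, coarse_category)]
  per_cat <- merge(per_cat, n_air, by = "ad_id")
  rows <- per_cat[, .(weighted_freq = sum(cat_weight * as.numeric(airings))),
                  by = .(coarse_category)]
  all_cats <- data.table(coarse_category = coarse_categories())
  rows <- merge(all_cats, rows, by = "coarse_category", all.x = TRUE)
  rows[is.na(weighted_freq), weighted_freq := 0]
  out <- rbind(
    rows[, .(category = coarse_category, weighted_freq)],
    data.table(category = "total", weighted_freq = total_wf)
  )
  out[, pct := weighted_freq / total_wf * 100]
  out[]
}
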