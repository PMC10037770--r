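#' Nutrition source tiers
#'
#' The lookup cascade order for product nutrition data: packaged-food label
#' database first, then the restaurant-menu database, then company Canadian
#' site, nutrition-facts tables found online, company US site, and finally a
#' similar-product substitute from the national nutrient file.
#'
#' @return Character vector of tier codes, highest priority first.
#' @export
nutrition_tiers <- function() {
  c("flip_2017", "menu_flip_2016", "company_ca_site", "nft_online",
    "company_us_site", "cnf_substitute")
}

#' Load a nutrient-threshold configuration
#'
#' Threshold values live in a versioned JSON config, never in code. The
#' config names, per nutrient column, a strict upper `limit` and the
#' added-ingredient flag column gating it; a product is unhealthy iff any
#' gated nutrient strictly exceeds its limit (`rule = "any_exceed"`).
#' The packaged default (`npm_thresholds_synthetic.json`) is a synthetic
#' stand-in for regulator-published values, usable for testing and
#' simulation only.
#'
#' @param path JSON file; default is the packaged synthetic config.
#' @return List with `version`, `basis`, `rule`, `thresholds`.
#' @export
npm_thresholds <- function(path = system.file("extdata",
                                              "npm_thresholds_synthetic.json",
                                              package = "adexpose")) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!all(c("basis", "rule", "thresholds") %in% names(cfg)))
    stop("threshold config needs basis, rule and thresholds")
  if (!identical(cfg$rule, "any_exceed"))
    stop("unsupported classification rule: ", cfg$rule)
  lims <- vapply(cfg$thresholds, function(t) as.numeric(t$limit), 0)
  if (any(!is.finite(lims) | lims <= 0))
    stop("threshold limits must be positive")
  cfg
}

#' Look up product nutrition through the source cascade
#'
#' Returns, for each product, the record from the first source tier that
#' contains it, tagging it with that tier; products found nowhere come back
#' with `missing = TRUE` and no amounts.
#'
#' @param product_ids character vector of products to resolve.
#' @param sources named list of nutrition tables in cascade priority order;
#'   names must be tiers from [nutrition_tiers()], each table a data.frame
#'   keyed by `product_id`.
#' @return `data.table` of profiles: `product_id`, nutrient and flag
#'   columns, `source_tier`, `missing`.
#' @export
lookup_nutrition <- function(product_ids, sources) {
  if (is.null(names(sources)) || !all(names(sources) %in% nutrition_tiers()))
    stop("sources must be a named list with tiers among: ",
         paste(nutrition_tiers(), collapse = ", "))
  ord <- order(match(names(sources), nutrition_tiers()))
  sources <- sources[ord]
  found <- list()
  remaining <- unique(product_ids)
  for (tier in names(sources)) {
    tab <- as.data.table(sources[[tier]])
    if (!"product_id" %in% names(tab))
      stop("nutrition table '", tier, "' lacks a product_id column")
    if (anyDuplicated(tab$product_id))
      stop("nutrition table '", tier, "' has duplicate product rows: ",
           paste(head(unique(tab$product_id[duplicated(tab$product_id)]), 5L),
                 collapse = ", "))
    hit <- tab[product_id %in% remaining]
    if (nrow(hit)) {
      hit[, source_tier := tier]
      hit[, missing := FALSE]
      found[[tier]] <- hit
      remaining <- setdiff(remaining, hit$product_id)
    }
  }
  out <- rbindlist(found, use.names = TRUE, fill = TRUE)
  if (length(remaining)) {
    out <- rbind(out,
                 data.table(product_id = remaining,
                            source_tier = NA_character_, missing = TRUE),
                 use.names = TRUE, fill = TRUE)
  }
  out[match(unique(product_ids), product_id)]
}

#' Classify products against nutrient thresholds
#'
#' A product is `unhealthy` iff, for any configured nutrient whose
#' added-ingredient flag is set on the product, the amount strictly exceeds
#' the limit; exactly at the limit is compliant (`healthy`). Products with
#' `missing = TRUE` come back `unclassified`.
#'
#' @param profiles nutrient profiles from [lookup_nutrition()]; must carry a
#'   `basis` column matching the config's basis (no silent conversion).
#' @param config threshold configuration from [npm_thresholds()].
#' @return `data.table` with `product_id`, `label` in
#'   `healthy`/`unhealthy`/`unclassified`.
#' @export
classify_products <- function(profiles, config = npm_thresholds()) {
  p <- as.data.table(profiles)
  if (!"missing" %in% names(p)) p <- copy(p)[, missing := FALSE]
  if ("basis" %in% names(p)) {
    bad <- p[missing == FALSE & !is.na(basis) & basis != config$basis]
    if (nrow(bad))
      stop("basis mismatch (config is ", config$basis, "): ",
           paste(head(bad$product_id, 5L), collapse = ", "))
  }
  exceed <- rep(FALSE, nrow(p))
  for (nut in names(config$thresholds)) {
    th <- config$thresholds[[nut]]
    if (!nut %in% names(p)) next
    amt <- p[[nut]]
    gate <- if (!is.null(th$added_flag) && th$added_flag %in% names(p))
      isTRUE_vec(p[[th$added_flag]]) else rep(TRUE, nrow(p))
    if (any(amt < 0, na.rm = TRUE))
      stop("negative nutrient amount in column ", nut)
    exceed <- exceed | (gate & !is.na(amt) & amt > as.numeric(th$limit))
  }
  lab <- ifelse(exceed, "unhealthy", "healthy")
  if ("missing" %in% names(p)) lab[p$missing] <- "unclassified"
  data.table(product_id = p$product_id, label = lab)
}

# logical coercion tolerant of NA (NA counts as flag unset)
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Classify one product profile
#'
#' Scalar wrapper over [classify_products()]; errors (rather than returning
#' `unclassified`) when the profile is missing, since a single-profile call
#' implies the caller expects data.
#'
#' @param profile one-row profile.
#' @param config threshold configuration.
#' @return `"healthy"` or `"unhealthy"`.
#' @export
classify_product <- function(profile, config = npm_thresholds()) {
  p <- as.data.table(profile)
  if (nrow(p) != 1L) stop("classify_product expects exactly one profile row")
  if (isTRUE(p$missing)) stop("profile is missing; nothing to classify")
  classify_products(p, config)$label
}

#' Classify advertisements by healthfulness
#'
#' An ad is `unhealthy` if any featured product is unhealthy; `healthy` if
#' it has at least one classifiable product and none unhealthy; and
#' `unclassified` for brand ads (no products) or when every product's
#' nutrition is missing. All products count, including any beyond the
#' 3-product frequency cap — the cap concerns weighting, not content.
#'
#' @param ads data.frame with `ad_id` (and optionally `n_products`).
#' @param ad_products data.frame linking `ad_id` to `product_id`.
#' @param product_labels output of [classify_products()].
#' @return `data.table` with `ad_id`, `label`; order-invariant in products.
#' @export
classify_ads <- function(ads, ad_products, product_labels) {
  ads <- as.data.table(ads)
  ap <- as.data.table(ad_products)
  pl <- as.data.table(product_labels)
  x <- merge(ap[, .(ad_id, product_id)], pl, by = "product_id", all.x = TRUE)
  x[is.na(label), label := "unclassified"]
  agg <- x[, .(label = if (any(label == "unhealthy")) "unhealthy"
               else if (any(label == "healthy")) "healthy"
               else "unclassified"),
           by = ad_id]
  out <- merge(ads[, .(ad_id)], agg, by = "ad_id", all.x = TRUE)
  out[is.na(label), label := "unclassified"] # brand ads: no product rows
  out[]
}

#' Healthy/unhealthy shares of classified advertising
#'
#' Shares of weighted advertising frequency (or exposure) over classified
#' ads only; unclassified frequency is excluded from the denominator and
#' reported separately as `unclassified_share` of the grand total when that
#' total is supplied.
#'
#' @param freq named numeric with elements `healthy` and `unhealthy`
#'   (weighted frequencies or exposures).
#' @param total_freq optional grand total including unclassified ads.
#' @return List: `healthy_pct`, `unhealthy_pct` (sum to 100), and
#'   `unclassified_pct` when `total_freq` given.
#' @examples
#' healthfulness_shares(c(healthy = 74617, unhealthy = 783855))
#' @export
healthfulness_shares <- function(freq, total_freq = NULL) {
  if (!all(c("healthy", "unhealthy") %in% names(freq)))
    stop("freq must name healthy and unhealthy components")
  classified <- sum(freq[c("healthy", "unhealthy")])
  if (classified <= 0) stop("no classified advertisements")
  out <- list(healthy_pct   = unname(freq[["healthy"]]) / classified * 100,
              unhealthy_pct = unname(freq[["unhealthy"]]) / classified * 100)
  if (!is.null(total_freq)) {
    if (total_freq < classified) stop("total_freq smaller than classified")
    out$unclassified_pct <- (total_freq - classified) / total_freq * 100
  }
  out
}
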