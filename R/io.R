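#' Write a market to the delimited-text/JSON interchange layout
#'
#' Emits the same files the ingestion readers consume: `airings.csv`
#' (station, start_iso8601, ad_id), `ads.json` (unique-ad records with
#' their product links), `category_map.csv`, one `nutrition/<tier>.csv`
#' per provenance tier, `panel.csv`, `viewing.csv`, `population.json` and
#' `codings.csv`.
#'
#' @param market an `ad_market` from [generate_market()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_market <- function(market, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "nutrition"), showWarnings = FALSE)
  iso <- function(x) format(x, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
  fwrite(market$airings[, .(station, start_iso8601 = iso(start), ad_id)],
         file.path(dir, "airings.csv"))
  ads <- merge(market$ads,
               market$ad_products[, .(products = list(product_id)),
                                  by = ad_id],
               by = "ad_id", all.x = TRUE)
  jsonlite::write_json(
    lapply(seq_len(nrow(ads)), function(i) list(
      ad_id = ads$ad_id[i], content_key = ads$content_key[i],
      language = ads$language[i], duration = ads$duration[i],
      products = if (is.null(ads$products[[i]])) character(0)
                 else ads$products[[i]])),
    file.path(dir, "ads.json"), auto_unbox = TRUE)
  fwrite(default_category_map()[, .(fine_code = fine_category,
                                    coarse_code = coarse_category)],
         file.path(dir, "category_map.csv"))
  fwrite(market$products, file.path(dir, "products.csv"))
  for (tier in names(market$nutrition_sources))
    fwrite(market$nutrition_sources[[tier]],
           file.path(dir, "nutrition", paste0(tier, ".csv")))
  fwrite(market$panel, file.path(dir, "panel.csv"))
  fwrite(market$viewing[, .(member_id, station,
                            start_iso8601 = iso(start),
                            end_iso8601 = iso(end))],
         file.path(dir, "viewing.csv"))
  pop <- market$config$population_by_stratum
  jsonlite::write_json(
    lapply(seq_len(nrow(pop)), function(i) as.list(pop[i])),
    file.path(dir, "population.json"), auto_unbox = TRUE)
  fwrite(market$codings, file.path(dir, "codings.csv"))
  invisible(dir)
}

#' Read an ad-occurrence log
#'
#' @param path CSV with columns `station`, `start_iso8601`, `ad_id`.
#' @return `data.table` with parsed POSIXct `start`.
#' @export
read_airings <- function(path) {
  x <- fread(path)
  x[, start := as.POSIXct(start_iso8601, tz = "UTC",
                          format = "%Y-%m-%dT%H:%M:%OS")]
  x[, .(station, start, ad_id)]
}

#' Read unique-ad JSON records
#'
#' @param path JSON array of records (`ad_id`, `content_key`, `language`,
#'   `duration`, `products`).
#' @return List: `ads` (`data.table` with `n_products`), `ad_products`.
#' @export
read_ads <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  ads <- rbindlist(lapply(recs, function(r)
    data.table(ad_id = r$ad_id, content_key = r$content_key,
               language = r$language, duration = as.numeric(r$duration),
               n_products = length(r$products))))
  ap <- rbindlist(lapply(recs, function(r)
    if (length(r$products))
      data.table(ad_id = r$ad_id, product_id = unlist(r$products))
    else NULL))
  list(ads = ads, ad_products = ap)
}

#' Read a fine-to-coarse category map
#'
#' @param path CSV with columns `fine_code`, `coarse_code`.
#' @param n_fine expected fine-code count (see [validate_category_map()]).
#' @return Validated `data.table` map.
#' @export
read_category_map <- function(path, n_fine = 57L) {
  x <- fread(path)
  setnames(x, c("fine_code", "coarse_code"),
           c("fine_category", "coarse_category"), skip_absent = TRUE)
  validate_category_map(x, n_fine)
  x
}

#' Read a panel roster
#'
#' @param path CSV with `member_id`, `age_group`, `sex`, `hh_band` (and
#'   optionally a precomputed `weight`).
#' @return `data.table`.
#' @export
read_panel <- function(path) fread(path)

#' Read viewing intervals
#'
#' @param path CSV with `member_id`, `station`, `start_iso8601`,
#'   `end_iso8601`.
#' @return Validated `data.table` with POSIXct `start`, `end`.
#' @export
read_viewing <- function(path) {
  x <- fread(path)
  x[, start := as.POSIXct(start_iso8601, tz = "UTC",
                          format = "%Y-%m-%dT%H:%M:%OS")]
  x[, end := as.POSIXct(end_iso8601, tz = "UTC",
                        format = "%Y-%m-%dT%H:%M:%OS")]
  validate_viewing(x[, .(member_id, station, start, end)])
  x[, .(member_id, station, start, end)]
}

#' Read population-by-stratum JSON
#'
#' @param path JSON array of `{age_group, sex, hh_band, population}`.
#' @return `data.table`.
#' @export
read_population <- function(path) {
  rbindlist(lapply(jsonlite::read_json(path, simplifyVector = FALSE),
                   as.data.table))
}

#' Read nutrition tables from a directory, one file per tier
#'
#' @param dir directory of `<tier>.csv` files named by
#'   [nutrition_tiers()] codes.
#' @return Named list of tables in cascade order, for
#'   [lookup_nutrition()].
#' @export
read_nutrition_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  tiers <- sub("\\.csv$", "", basename(files))
  bad <- setdiff(tiers, nutrition_tiers())
  if (length(bad)) stop("unknown nutrition tiers: ", paste(bad, collapse = ", "))
  src <- lapply(files, fread)
  names(src) <- tiers
  src[order(match(tiers, nutrition_tiers()))]
}

#' Read technique codings
#'
#' @param path CSV with `ad_id`, optional `coder_id`, and one logical
#'   column per technique.
#' @return `data.table`.
#' @export
read_codings <- function(path) fread(path)
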