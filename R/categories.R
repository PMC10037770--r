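#' Coarse food categories
#'
#' The 13 coarse categories that the 57 fine advertising categories aggregate
#' into: bread; sweet baked goods/desserts; candy and chocolate; breakfast
#' food; dairy; condiments; entrees and meat; fruits and vegetables;
#' beverages (excluding milk and water); miscellaneous; snacks; water;
#' restaurants.
#'
#' @return Character vector of the 13 coarse category codes.
#' @export
coarse_categories <- function() {
  c("bread", "sweet_baked", "candy_chocolate", "breakfast", "dairy",
    "condiments", "entrees", "fruits_vegetables", "beverages",
    "miscellaneous", "snacks", "water", "restaurants")
}

#' Default fine-to-coarse category map
#'
#' Builds a total, surjective map from 57 fine category codes onto the 13
#' coarse codes. Real fine categories are proprietary licensing metadata, so
#' the shipped map uses systematic synthetic codes (`bread_01`, ...,
#' `restaurants_05`); any user map with the same two-column shape can be
#' substituted via [read_category_map()].
#'
#' @return `data.table` with columns `fine_category`, `coarse_category`
#'   (57 rows, all 13 coarse codes present).
#' @export
default_category_map <- function() {
  coarse <- coarse_categories()
  # 13 * 4 = 52; five categories carry an extra fine code to reach 57
  sizes <- rep(4L, 13L)
  sizes[seq_len(5L)] <- 5L
  fine <- unlist(mapply(function(cc, k) sprintf("%s_%02d", cc, seq_len(k)),
                        coarse, sizes, SIMPLIFY = FALSE), use.names = FALSE)
  map <- data.table(
    fine_category   = fine,
    coarse_category = rep(coarse, sizes)
  )
  validate_category_map(map)
  map
}

#' Validate a category map
#'
#' A valid map is total over its fine codes (no duplicates, no NA) and
#' surjective onto the 13 coarse codes.
#'
#' @param map data.frame with columns `fine_category`, `coarse_category`.
#' @param n_fine expected number of fine codes (default 57; pass `NULL` to
#'   skip the count check for reduced test maps).
#' @return The map, invisibly, as a `data.table`.
#' @export
validate_category_map <- function(map, n_fine = 57L) {
  map <- as.data.table(map)
  req <- c("fine_category", "coarse_category")
  if (!all(req %in% names(map)))
    stop("category map must have columns: ", paste(req, collapse = ", "))
  if (anyNA(map$fine_category) || anyNA(map$coarse_category))
    stop("category map contains missing codes")
  if (anyDuplicated(map$fine_category))
    stop("fine categories mapped more than once: ",
         paste(unique(map$fine_category[duplicated(map$fine_category)]),
               collapse = ", "))
  bad <- setdiff(unique(map$coarse_category), coarse_categories())
  if (length(bad))
    stop("unknown coarse categories: ", paste(bad, collapse = ", "))
  missing_coarse <- setdiff(coarse_categories(), map$coarse_category)
  if (length(missing_coarse))
    stop("map not surjective; coarse categories unused: ",
         paste(missing_coarse, collapse = ", "))
  if (!is.null(n_fine) && nrow(map) != n_fine)
    stop("expected ", n_fine, " fine categories, got ", nrow(map))
  invisible(map)
}

#' Map fine category codes to coarse codes
#'
#' @param fine character vector of fine category codes.
#' @param map a category map (defaults to [default_category_map()]).
#' @return Character vector of coarse codes, same length as `fine`.
#' @export
map_fine_to_coarse <- function(fine, map = default_category_map()) {
  map <- as.data.table(map)
  idx <- match(fine, map$fine_category)
  if (anyNA(idx) && !anyNA(fine)) {
    bad <- unique(fine[is.na(idx)])
    stop("unmapped fine categories: ", paste(bad, collapse = ", "))
  }
  map$coarse_category[idx]
}
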