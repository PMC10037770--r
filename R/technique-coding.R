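#' The 22-technique marketing codebook
#'
#' Persuasive techniques recorded present/absent once per ad during content
#' analysis, regardless of how many products the ad features. Codes cover
#' child-directed devices (actors, products, characters, language, special
#' effects, themes, spokes-characters, parent-child situations, licensed
#' characters, cross-promotions, incentives), adolescent-directed devices
#' (actors, language, music, themes, incentives, humour) and general
#' appeals (contests, celebrity endorsement, health claims, price
#' promotions, online calls to action).
#'
#' @return `data.table` with columns `code`, `description` (22 rows).
#' @export
technique_codebook <- function() {
  data.table(
    code = c(
      "child_actor", "child_product", "child_characters", "child_language",
      "child_special_effects", "child_themes", "spokes_characters",
      "parent_child", "licensed_characters", "cross_promotions",
      "child_incentives", "teen_actor", "teen_language", "teen_music",
      "teen_themes", "teen_incentives", "teen_humour", "contest",
      "celebrity", "health_claim", "price_promotion",
      "call_to_action_online"),
    description = c(
      "Main characters are children or have childlike voices",
      "Product appeals to children by type, shape, colour or design",
      "Cartoon, animal or fantasy characters",
      "Language used by or directed at children",
      "Lettering, effects, animation or jingles appealing to children",
      "Fantasy, magic, adventure or virtual-world themes",
      "Brand-owned spokes-characters",
      "Plays on the parent-child or authority relationship",
      "Licensed characters from children's media",
      "Cross-promotions with movies or shows watched by children",
      "Free gifts aimed at children",
      "Youth 12-17 prominently featured",
      "Adolescent slang or phrasing",
      "Music appealing to adolescents",
      "Themes based on adolescent activities and interests",
      "Incentives aimed at adolescents",
      "Adolescent-directed humour",
      "Contest or sweepstakes with prizes",
      "Celebrity endorsement",
      "Health or nutrition claims",
      "Price premiums, rebates or purchase calls to action",
      "Sending viewers online to brand website or app")
  )
}

#' Randomly assign ads to coders
#'
#' Partitions unique ads among coders for content analysis; group sizes
#' differ by at most one and the split is reproducible from the seed. RNG
#' state of the caller is left untouched.
#'
#' @param ad_ids character vector of unique-ad identifiers.
#' @param n_coders number of coders (>= 1).
#' @param seed integer seed.
#' @return Named list, one ad-id vector per coder (`coder_1`, ...).
#' @export
assign_ads <- function(ad_ids, n_coders, seed = 1L) {
  if (n_coders < 1L) stop("n_coders must be >= 1")
  perm <- with_substream(seed, "assign_ads", sample.int(length(ad_ids)))
  grp <- rep_len(seq_len(n_coders), length(ad_ids))
  split(ad_ids[perm], sprintf("coder_%d", grp))
}

#' Inter-rater reliability of technique codings
#'
#' Computes agreement between coders over the items they all coded, either
#' as percent agreement or as Cohen's kappa. Percent agreement is reported
#' at item level (identical full 22-technique vectors) with per-technique
#' agreement alongside; kappa is computed per technique for each coder pair
#' and averaged. The headline value of a training reliability exercise
#' depends on which statistic is chosen, so the metric is always explicit
#' in the output.
#'
#' @param codings data.frame with `ad_id`, `coder_id` and one logical
#'   column per technique.
#' @param metric `"percent_agreement"` or `"cohen_kappa"`.
#' @return List: `metric`, `value` (overall), `n_items`, `per_technique`
#'   (named numeric).
#' @export
interrater_reliability <- function(codings,
                                   metric = c("percent_agreement",
                                              "cohen_kappa")) {
  metric <- match.arg(metric)
  cd <- as.data.table(codings)
  tech_cols <- setdiff(names(cd), c("ad_id", "coder_id", "round"))
  coders <- unique(cd$coder_id)
  if (length(coders) < 2L) stop("need at least two coders")
  shared <- Reduce(intersect, split(cd$ad_id, cd$coder_id))
  if (!length(shared)) stop("coders share no coded items")
  cd <- cd[ad_id %in% shared]
  wide <- lapply(coders, function(co) {
    x <- cd[coder_id == co][match(shared, ad_id)]
    as.matrix(x[, tech_cols, with = FALSE]) * 1L
  })

  if (metric == "percent_agreement") {
    pairs <- utils::combn(length(coders), 2L, simplify = FALSE)
    item_agree <- per_tech <- 0
    per_tech <- setNames(numeric(length(tech_cols)), tech_cols)
    for (pr in pairs) {
      eq <- wide[[pr[1]]] == wide[[pr[2]]]
      item_agree <- item_agree + mean(rowSums(!eq) == 0L)
      per_tech <- per_tech + colMeans(eq)
    }
    list(metric = metric,
         value = item_agree / length(pairs),
         n_items = length(shared),
         per_technique = per_tech / length(pairs))
  } else {
    pairs <- utils::combn(length(coders), 2L, simplify = FALSE)
    per_tech <- setNames(numeric(length(tech_cols)), tech_cols)
    for (pr in pairs) {
      k <- vapply(seq_along(tech_cols), function(j)
        cohen_kappa(wide[[pr[1]]][, j], wide[[pr[2]]][, j]), 0)
      per_tech <- per_tech + k
    }
    per_tech <- per_tech / length(pairs)
    list(metric = metric,
         value = mean(per_tech, na.rm = TRUE),
         n_items = length(shared),
         per_technique = per_tech)
  }
}

#' Cohen's kappa for two binary ratings
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)`. Perfect observed
#' agreement is kappa 1 even when marginals are degenerate (both coders
#' constant), where the textbook formula is 0/0; a degenerate chance
#' expectation with imperfect agreement is `NA`.
#'
#' @param x,y integer/logical vectors of equal length (0/1).
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohen_kappa <- function(x, y) {
  stopifnot(length(x) == length(y))
  x <- as.integer(as.logical(x)); y <- as.integer(as.logical(y))
  po <- mean(x == y)
  if (po == 1) return(1)
  pe <- mean(x) * mean(y) + (1 - mean(x)) * (1 - mean(y))
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Consensus coding across coders
#'
#' Collapses multiple codings of the same ads into one consensus record per
#' ad by per-technique majority vote; exact ties are left `NA` and flagged
#' `pending` for manual settlement, mirroring a researcher-led consensus
#' step.
#'
#' @param codings data.frame with `ad_id`, `coder_id` and technique
#'   columns; every ad must have >= 2 codings.
#' @return `data.table` with `ad_id`, technique columns (logical, `NA`
#'   where tied), `round = "consensus"`, `pending` (any unresolved
#'   technique).
#' @export
resolve_consensus <- function(codings) {
  cd <- as.data.table(codings)
  tech_cols <- setdiff(names(cd), c("ad_id", "coder_id", "round"))
  n_cod <- cd[, .N, by = ad_id]
  if (any(n_cod$N < 2L))
    stop("ads with fewer than two codings: ",
         paste(head(n_cod$ad_id[n_cod$N < 2L], 5L), collapse = ", "))
  maj <- function(v) {
    yes <- sum(v); no <- length(v) - yes
    if (yes > no) TRUE else if (no > yes) FALSE else NA
  }
  out <- cd[, lapply(.SD, maj), by = ad_id, .SDcols = tech_cols]
  out[, round := "consensus"]
  out[, pending := rowSums(is.na(.SD)) > 0L, .SDcols = tech_cols]
  out[]
}

# Table-derived default prevalence of each technique among unique-ad
# weighted frequency; used by the synthetic generator.
technique_prevalence <- function() {
  c(child_actor = 0.203, child_product = 0.303, child_characters = 0.206,
    child_language = 0.056, child_special_effects = 0.255,
    child_themes = 0.138, spokes_characters = 0.194, parent_child = 0.189,
    licensed_characters = 0.006, cross_promotions = 0.032,
    child_incentives = 0.011, teen_actor = 0.137, teen_language = 0.022,
    teen_music = 0.018, teen_themes = 0.183, teen_incentives = 0.003,
    teen_humour = 0.020, contest = 0.036, celebrity = 0.047,
    health_claim = 0.323, price_promotion = 0.212,
    call_to_action_online = 0.347)
}
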