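#' Recipe-based wheat-flour share of a mixed-flour item
#'
#' For items made from a mix of flours, the grams of white wheat flour per
#' 100 g of the item as consumed are the item's total flour content times the
#' summed share of its wheat components. Flour content is normally resolved
#' once, when the food composition table is built, so this is a
#' table-construction helper rather than a per-recall computation.
#'
#' @param flour_type character vector, `"wheat"` or `"other"`, one per recipe
#'   component.
#' @param share fractions of the item's total flour per component; must sum
#'   to 1.
#' @param total_flour_per_100g grams of flour (all types) per 100 g of item.
#' @return Grams of white wheat flour per 100 g of item.
#' @examples
#' wheat_fraction(c("wheat", "other"), c(0.5, 0.5), 40)  # 20
#' @export
wheat_fraction <- function(flour_type, share, total_flour_per_100g) {
  stopifnot(length(flour_type) == length(share), total_flour_per_100g >= 0)
  if (!all(flour_type %in% c("wheat", "other"))) {
    stop("flour_type must be 'wheat' or 'other'", call. = FALSE)
  }
  if (abs(sum(share) - 1) > 1e-9) {
    stop("recipe flour shares must sum to 1", call. = FALSE)
  }
  total_flour_per_100g * sum(share[flour_type == "wheat"])
}

#' Per-portion flour and calcium arithmetic
#'
#' `flour_grams()` converts grams of an item as consumed into grams of white
#' wheat flour using the item's `wheat_flour_g_per_100g`; `calcium_mg()` does
#' the analogous conversion for calcium. Both are linear in grams.
#'
#' @param wheat_flour_g_per_100g grams of wheat flour per 100 g of item,
#'   in `[0, 100]`.
#' @param calcium_mg_per_100g mg of calcium per 100 g of item, `>= 0`.
#' @param grams grams consumed, `>= 0`.
#' @return Grams of wheat flour / mg of calcium in the portion.
#' @export
flour_grams <- function(wheat_flour_g_per_100g, grams) {
  stopifnot(all(wheat_flour_g_per_100g >= 0), all(wheat_flour_g_per_100g <= 100))
  if (any(grams < 0)) stop("grams consumed must be >= 0", call. = FALSE)
  grams * wheat_flour_g_per_100g / 100
}

#' @rdname flour_grams
#' @export
calcium_mg <- function(calcium_mg_per_100g, grams) {
  stopifnot(all(calcium_mg_per_100g >= 0))
  if (any(grams < 0)) stop("grams consumed must be >= 0", call. = FALSE)
  grams * calcium_mg_per_100g / 100
}

validate_foods <- function(foods) {
  need <- c("item_id", "calcium_mg_per_100g", "wheat_flour_g_per_100g",
            "is_supplement")
  if (!all(need %in% names(foods))) {
    stop("foods table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(foods$item_id)) {
    stop("duplicate item_id in foods table", call. = FALSE)
  }
  stopifnot(all(foods$calcium_mg_per_100g >= 0),
            all(foods$wheat_flour_g_per_100g >= 0),
            all(foods$wheat_flour_g_per_100g <= 100))
  foods
}

#' Aggregate recall records to person-day calcium and flour totals
#'
#' Joins each recall record to the food composition table and sums calcium
#' (mg) and white wheat flour (g) over all records of a participant-day.
#' Supplements contribute calcium but never flour. Records are put in a
#' canonical order (participant, day, item, grams) before summation, so
#' totals are bit-identical under any permutation of the input rows.
#'
#' @param recalls data frame with columns `participant_id`, `day` (1 or 2),
#'   `item_id`, `grams`.
#' @param foods data frame with columns `item_id`, `calcium_mg_per_100g`,
#'   `wheat_flour_g_per_100g`, `is_supplement`.
#' @return Data frame with one row per observed participant-day:
#'   `participant_id`, `day`, `calcium` (mg/d), `flour` (g/d).
#' @export
person_day_totals <- function(recalls, foods) {
  foods <- validate_foods(foods)
  need <- c("participant_id", "day", "item_id", "grams")
  if (!all(need %in% names(recalls))) {
    stop("recalls table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(recalls) == 0L) {
    return(data.frame(participant_id = character(), day = integer(),
                      calcium = numeric(), flour = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (any(recalls$grams < 0)) stop("grams consumed must be >= 0", call. = FALSE)
  if (!all(recalls$day %in% c(1L, 2L))) {
    stop("recall day must be 1 or 2", call. = FALSE)
  }
  idx <- match(recalls$item_id, foods$item_id)
  if (anyNA(idx)) {
    bad <- unique(recalls$item_id[is.na(idx)])
    stop("recall items missing from foods table: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  ca <- calcium_mg(foods$calcium_mg_per_100g[idx], recalls$grams)
  fl <- flour_grams(foods$wheat_flour_g_per_100g[idx], recalls$grams)
  fl[foods$is_supplement[idx]] <- 0
  ord <- order(recalls$participant_id, recalls$day, recalls$item_id,
               recalls$grams)
  key <- interaction(recalls$participant_id[ord], recalls$day[ord],
                     drop = TRUE, lex.order = TRUE)
  first <- !duplicated(key)
  data.frame(
    participant_id = recalls$participant_id[ord][first],
    day = recalls$day[ord][first],
    calcium = as.numeric(rowsum(ca[ord], key, reorder = FALSE)),
    flour = as.numeric(rowsum(fl[ord], key, reorder = FALSE)),
    stringsAsFactors = FALSE
  )
}
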