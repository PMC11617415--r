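#' Dietary reference value (DRI) tables for calcium
#'
#' Age- and sex-specific estimated average requirements (EAR) and tolerable
#' upper intake levels (UL), organised in half-open age intervals
#' `[age_lo, age_hi)` — an age exactly at a boundary belongs to the upper
#' group. Two tables ship with the package: `"iom"` (default), the harmonized
#' IOM-derived set with UL 2000 mg/d from age 51 upwards, and `"efsa_ul"`, a
#' sensitivity variant using the EFSA adult UL of 2500 mg/d at all adult ages.
#' Both share the anchor values EAR = 1100 mg/d for ages 9 to <19 and (in the
#' default table) UL = 2000 mg/d at 71+. Values other than those anchors are
#' editable configuration: pass your own CSV to override them.
#'
#' The CSV format has columns `sex` (`F`, `M`, or `ALL` for sex-pooled child
#' groups), `age_lo`, `age_hi` (empty for an open-ended upper bound),
#' `ear_mg`, `ul_mg`. Validation requires `0 < ear < ul` per row, and for each
#' sex the applicable rows must tile an age range with no overlaps or gaps.
#'
#' @param path path to a DRI CSV; when `NULL` the shipped `variant` is used.
#' @param variant one of `"iom"` or `"efsa_ul"`.
#' @return A data frame of class `dri_table` with columns `group` (label),
#'   `sex`, `age_lo`, `age_hi` (`Inf` when open-ended), `ear_mg`, `ul_mg`.
#' @examples
#' dri <- load_dri_table()
#' lookup_dri(assign_group(10, "F", dri), dri)$ear_mg  # 1100
#' @export
load_dri_table <- function(path = NULL, variant = c("iom", "efsa_ul")) {
  if (is.null(path)) {
    variant <- match.arg(variant)
    path <- system.file("extdata", paste0("dri_", variant, ".csv"),
                        package = "fortisim", mustWork = TRUE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(sex = "character"))
  need <- c("sex", "age_lo", "age_hi", "ear_mg", "ul_mg")
  if (!all(need %in% names(raw))) {
    stop("DRI file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  raw$age_hi[is.na(raw$age_hi)] <- Inf
  for (i in seq_len(nrow(raw))) {
    r <- raw[i, ]
    if (!r$sex %in% c("F", "M", "ALL")) {
      stop(sprintf("DRI row %d: sex must be F, M or ALL", i), call. = FALSE)
    }
    if (!is.finite(r$age_lo) || r$age_lo < 0 || !(r$age_lo < r$age_hi)) {
      stop(sprintf("DRI row %d: need 0 <= age_lo < age_hi", i), call. = FALSE)
    }
    if (is.na(r$ear_mg) || is.na(r$ul_mg) || r$ear_mg <= 0 ||
        r$ear_mg >= r$ul_mg) {
      stop(sprintf("DRI row %d: need 0 < ear_mg < ul_mg", i), call. = FALSE)
    }
  }
  # per-sex partition check: rows for sex S are those labelled S or ALL
  for (s in c("F", "M")) {
    rows <- raw[raw$sex %in% c(s, "ALL"), ]
    rows <- rows[order(rows$age_lo), ]
    if (nrow(rows) > 1) {
      lo <- rows$age_lo[-1]; hi <- rows$age_hi[-nrow(rows)]
      if (any(lo < hi)) {
        stop(sprintf("DRI table: overlapping age intervals for sex %s", s),
             call. = FALSE)
      }
      if (any(lo > hi)) {
        stop(sprintf("DRI table: gap in age coverage for sex %s", s),
             call. = FALSE)
      }
    }
  }
  raw$group <- group_label(raw$sex, raw$age_lo, raw$age_hi)
  out <- raw[, c("group", "sex", "age_lo", "age_hi", "ear_mg", "ul_mg")]
  class(out) <- c("dri_table", "data.frame")
  out
}

group_label <- function(sex, age_lo, age_hi) {
  span <- ifelse(is.finite(age_hi),
                 sprintf("%g-<%g", age_lo, age_hi),
                 sprintf("%g+", age_lo))
  ifelse(sex == "ALL", span, paste(sex, span))
}

#' Assign participants to age-sex reference groups
#'
#' Maps an age (years) and sex to the unique DRI group whose half-open
#' interval `[age_lo, age_hi)` contains the age. Sex-pooled (`ALL`) child
#' groups match either sex.
#'
#' @param age numeric vector of ages in years.
#' @param sex character vector, `"F"` or `"M"` (recycled if length 1).
#' @param dri a `dri_table`, default [load_dri_table()].
#' @return Character vector of group labels.
#' @examples
#' assign_group(c(10, 4, 75), c("F", "M", "M"))
#' @export
assign_group <- function(age, sex, dri = load_dri_table()) {
  stopifnot(inherits(dri, "dri_table"))
  if (length(sex) == 1L) sex <- rep(sex, length(age))
  stopifnot(length(sex) == length(age))
  if (!all(sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  out <- character(length(age))
  for (i in seq_along(age)) {
    if (is.na(age[i]) || age[i] < min(dri$age_lo)) {
      stop(sprintf("age %s is below the supported range (min %g)",
                   format(age[i]), min(dri$age_lo)), call. = FALSE)
    }
    hit <- which((dri$sex == sex[i] | dri$sex == "ALL") &
                   dri$age_lo <= age[i] & age[i] < dri$age_hi)
    if (length(hit) != 1L) {
      stop(sprintf("no unique DRI group for age %g sex %s", age[i], sex[i]),
           call. = FALSE)
    }
    out[i] <- dri$group[hit]
  }
  out
}

#' Look up reference values for a group
#'
#' @param group a group label as produced by [assign_group()].
#' @param dri a `dri_table`.
#' @return The single matching `dri_table` row (with `ear_mg`, `ul_mg`).
#' @export
lookup_dri <- function(group, dri = load_dri_table()) {
  stopifnot(inherits(dri, "dri_table"), length(group) == 1L)
  hit <- which(dri$group == group)
  if (length(hit) != 1L) {
    stop(sprintf("group '%s' not found in DRI table", group), call. = FALSE)
  }
  dri[hit, ]
}
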