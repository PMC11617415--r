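#' Apply a flour-fortification scenario to person-day totals
#'
#' Adds `level / 100` mg of calcium per gram of wheat flour to every
#' person-day: `calcium' = calcium + flour * level / 100`, flour unchanged.
#' The arithmetic is exact per record, so applying level `a` then level `b`
#' equals applying `a + b` in one step.
#'
#' @param totals person-day totals (from [person_day_totals()]), with
#'   columns `calcium` (mg/d) and `flour` (g/d).
#' @param level mg of calcium added per 100 g of wheat flour (`>= 0`).
#' @return The totals with fortified calcium.
#' @export
apply_scenario <- function(totals, level) {
  if (length(level) != 1L || is.na(level) || level < 0) {
    stop("fortification level must be a single non-negative number",
         call. = FALSE)
  }
  stopifnot(all(c("calcium", "flour") %in% names(totals)))
  totals$calcium <- totals$calcium + totals$flour * level / 100
  totals
}

#' Initial gap between a group's requirement and its mean usual intake
#'
#' The mg/d shortfall used to size a fortification level:
#' `max(0, ear - mean_usual)`.
#'
#' @param mean_usual group mean usual calcium intake, mg/d.
#' @param ear the group's estimated average requirement, mg/d.
#' @return mg/d, floored at 0.
#' @export
initial_gap <- function(mean_usual, ear) {
  stopifnot(all(mean_usual >= 0), all(ear >= 0))
  pmax(0, ear - mean_usual)
}

#' Fortification level needed to close a gap through flour
#'
#' Divides a mg/d calcium gap by the group's mean flour intake to get the
#' mg-per-100-g-flour level that would close it on average:
#' `gap / (mean_flour / 100)`.
#'
#' @param gap mg/d, e.g. from [initial_gap()].
#' @param mean_flour mean daily wheat-flour intake, g/d (`> 0`).
#' @return mg calcium per 100 g flour.
#' @export
required_level <- function(gap, mean_flour) {
  stopifnot(all(gap >= 0))
  if (any(mean_flour <= 0)) {
    stop("required_level is undefined when mean flour intake is 0",
         call. = FALSE)
  }
  gap / (mean_flour / 100)
}

#' Evaluate fortification scenarios per age-sex group
#'
#' The full simulation: person-day totals are fortified at each level, the
#' usual-intake model is re-fitted per group and level (the transform and
#' variance components are re-estimated on the fortified totals, since
#' fortification changes the skewness of the distribution), and adequacy is
#' summarised against the group's EAR and UL. Level 0 (the unfortified
#' baseline) is always included and anchors the initial gap.
#'
#' @param dataset a `survey_dataset` (participants with `age`, `sex`,
#'   `weight`; recalls; foods) — synthetic or loaded via [read_survey()].
#' @param levels fortification levels in mg calcium per 100 g flour;
#'   0 is added if absent.
#' @param dri a `dri_table`.
#' @param safety_cutoff flag scenarios where `% above UL` exceeds this
#'   percentage (default 0.5); an annotation, not a failure.
#' @param quad_order Gauss-Hermite order passed to [usual_intake()].
#' @param gap_stat use the `"mean"` (default) or `"median"` usual intake
#'   when computing the initial gap.
#' @param keep_fits if `TRUE`, attach per-participant usual intakes for every
#'   group and level (attribute `"usual"`) and the per-group baseline
#'   transform/variance parameters (attribute `"components"`), for plotting
#'   and export.
#' @return Data frame of class `adequacy_summary`, one row per group and
#'   level: `group`, `level`, `n`, `pct_flour_consumers`, `mean_flour`,
#'   `mean_calcium` (mean usual intake, mg/d), `pct_below_ear`,
#'   `pct_above_ul`, `initial_gap`, `safety_flag`.
#' @export
evaluate_scenarios <- function(dataset, levels = c(0, 200, 400, 500),
                               dri = load_dri_table(), safety_cutoff = 0.5,
                               quad_order = 21,
                               gap_stat = c("mean", "median"),
                               keep_fits = FALSE) {
  gap_stat <- match.arg(gap_stat)
  stopifnot(inherits(dataset, "survey_dataset"))
  if (any(levels < 0)) stop("fortification levels must be >= 0", call. = FALSE)
  levels <- sort(unique(c(0, levels)))
  pp <- dataset$participants
  stopifnot(all(c("participant_id", "age", "sex", "weight") %in% names(pp)))
  if (nrow(pp) == 0L) stop("dataset has no participants", call. = FALSE)
  pp$group <- assign_group(pp$age, pp$sex, dri)
  totals <- person_day_totals(dataset$recalls, dataset$foods)
  m <- match(totals$participant_id, pp$participant_id)
  if (anyNA(m)) stop("recalls reference unknown participants", call. = FALSE)
  totals$weight <- pp$weight[m]
  totals$group <- pp$group[m]

  rows <- list(); usuals <- list(); comp_list <- list(); skipped <- character()
  for (grp in dri$group) {
    tg <- totals[totals$group == grp, , drop = FALSE]
    if (nrow(tg) == 0L || length(unique(tg$participant_id)) < 2L) {
      skipped <- c(skipped, grp)
      next
    }
    ref <- lookup_dri(grp, dri)
    d1 <- tg[tg$day == 1, , drop = FALSE]
    pct_cons <- weighted_pct_above(d1$flour, 0, d1$weight)
    mean_flour <- weighted_mean(d1$flour, d1$weight)
    gap <- NA_real_
    for (lev in levels) {
      tf <- apply_scenario(tg, lev)
      fit <- usual_intake(calcium ~ participant_id, tf, weights = weight,
                          quad_order = quad_order)
      s <- summary(fit, ear = ref$ear_mg, ul = ref$ul_mg)
      if (lev == 0) {
        base_stat <- if (gap_stat == "mean") s$mean
                     else unname(weighted_quantile(
                       fit$participants$usual, fit$participants$weight, 0.5))
        gap <- initial_gap(base_stat, ref$ear_mg)
        if (keep_fits) {
          comp_list[[grp]] <- c(as.list(coef(fit)),
                                list(truncated = fit$components$truncated,
                                     degenerate = fit$transform$degenerate,
                                     n_replicated = fit$components$n_replicated))
        }
      }
      if (keep_fits) {
        usuals[[length(usuals) + 1L]] <- data.frame(
          participant_id = fit$participants$participant_id,
          group = grp, level = lev, usual = fit$participants$usual,
          weight = fit$participants$weight, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, level = lev,
        n = length(unique(tg$participant_id)),
        pct_flour_consumers = pct_cons, mean_flour = mean_flour,
        mean_calcium = s$mean,
        pct_below_ear = s$pct_below_ear, pct_above_ul = s$pct_above_ul,
        initial_gap = gap,
        safety_flag = s$pct_above_ul > safety_cutoff,
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped) && length(skipped) < nrow(dri)) {
    warning("groups omitted (no or too few participants): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (!length(rows)) stop("no group has enough participants", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "safety_cutoff") <- safety_cutoff
  if (keep_fits) {
    attr(out, "usual") <- do.call(rbind, usuals)
    attr(out, "components") <- comp_list
  }
  class(out) <- c("adequacy_summary", "data.frame")
  out
}

#' @export
print.adequacy_summary <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE) & !(names(y) %in% c("level", "n"))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
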