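#' Default per-group generator parameters
#'
#' One row per age-sex reference group, giving the sampling share of the
#' total sample and the latent usual-intake model: usual calcium and usual
#' flour are lognormal, with group means chosen to emulate the descriptive
#' envelope of the Argentine urban survey the pipeline targets — group mean
#' calcium between roughly 400 and 600 mg/d, mean wheat flour between about
#' 55 and 110 g/d (highest in men aged 19 to <51, lowest in women 51+), and
#' at least 95% flour consumers. These defaults are emulation, not ground
#' truth.
#'
#' @return Data frame with columns `group`, `sex`, `age_lo`, `age_hi`,
#'   `share`, `ca_mean` (mg/d), `ca_sdlog`, `flour_mean` (g/d, among
#'   consumers), `flour_sdlog`, `p_flour`.
#' @export
default_group_params <- function() {
  dri <- load_dri_table()
  p <- data.frame(
    group = dri$group, sex = dri$sex, age_lo = dri$age_lo, age_hi = dri$age_hi,
    stringsAsFactors = FALSE
  )
  pick <- function(...) {
    v <- c(...)
    unname(v[p$group])
  }
  p$share <- pick("1-<4" = 0.10, "4-<9" = 0.14,
                  "F 9-<14" = 0.07, "M 9-<14" = 0.07,
                  "F 14-<19" = 0.07, "M 14-<19" = 0.07,
                  "F 19-<31" = 0.07, "M 19-<31" = 0.07,
                  "F 31-<51" = 0.07, "M 31-<51" = 0.07,
                  "F 51-<71" = 0.05, "M 51-<71" = 0.05,
                  "F 71+" = 0.05, "M 71+" = 0.05)
  p$share <- p$share / sum(p$share)
  p$ca_mean <- pick("1-<4" = 560, "4-<9" = 530,
                    "F 9-<14" = 480, "M 9-<14" = 510,
                    "F 14-<19" = 450, "M 14-<19" = 520,
                    "F 19-<31" = 450, "M 19-<31" = 520,
                    "F 31-<51" = 460, "M 31-<51" = 510,
                    "F 51-<71" = 440, "M 51-<71" = 470,
                    "F 71+" = 420, "M 71+" = 440)
  p$ca_sdlog <- 0.45
  p$flour_mean <- pick("1-<4" = 56, "4-<9" = 76,
                       "F 9-<14" = 92, "M 9-<14" = 98,
                       "F 14-<19" = 90, "M 14-<19" = 106,
                       "F 19-<31" = 85, "M 19-<31" = 110,
                       "F 31-<51" = 80, "M 31-<51" = 102,
                       "F 51-<71" = 59, "M 51-<71" = 86,
                       "F 71+" = 55, "M 71+" = 70)
  p$flour_sdlog <- 0.55
  p$p_flour <- 0.96
  p
}

#' Synthetic-survey configuration
#'
#' Bundles everything [generate_survey()] needs: the per-group latent-intake
#' parameters, the within-person day-to-day coefficients of variation, the
#' replicate-recall design fraction, supplement use, regions with target
#' weighted shares, and the seed. Within-person noise is multiplicative
#' lognormal; a CV is converted internally to a log-scale SD via
#' `sdlog^2 = log(1 + CV^2)`.
#'
#' @param n total number of participants (allocated over groups by `share`).
#' @param groups per-group parameter table, see [default_group_params()].
#' @param replicate_fraction fraction of each group receiving a second recall
#'   (exact count, `round(fraction * n_group)`), default 0.20.
#' @param cv_calcium,cv_flour within-person day-to-day CVs.
#' @param p_supplement probability of being a daily calcium-supplement user.
#' @param supplement_dose mg/d delivered by the supplement.
#' @param regions named vector of target weighted region shares (normalised).
#' @param seed integer seed; the same config and seed reproduce the dataset
#'   exactly.
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(n = 5000,
                          groups = default_group_params(),
                          replicate_fraction = 0.2,
                          cv_calcium = 0.35,
                          cv_flour = 0.45,
                          p_supplement = 0.001,
                          supplement_dose = 500,
                          regions = c(GBA = 0.32, Pampeana = 0.28, NOA = 0.12,
                                      NEA = 0.10, Cuyo = 0.08, Patagonia = 0.10),
                          seed = 1L) {
  stopifnot(n >= 0, is.data.frame(groups),
            cv_calcium >= 0, cv_flour >= 0,
            p_supplement >= 0, p_supplement <= 1, supplement_dose >= 0,
            all(groups$p_flour >= 0 & groups$p_flour <= 1),
            all(regions > 0), length(names(regions)) == length(regions))
  if (replicate_fraction < 0 || replicate_fraction > 1) {
    stop("replicate_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(n = n, groups = groups,
                 replicate_fraction = replicate_fraction,
                 cv_calcium = cv_calcium, cv_flour = cv_flour,
                 p_supplement = p_supplement,
                 supplement_dose = supplement_dose,
                 regions = regions / sum(regions), seed = as.integer(seed)),
            class = "survey_config")
}

# cv -> lognormal sdlog for a mean-one multiplicative noise
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# Allocate n over shares. When n is a multiple of 5, apportion in multiples
# of 5 (largest remainder on n/5) so that round(0.2 * n_g) makes the overall
# two-recall share exactly the design fraction.
allocate_groups <- function(n, share) {
  unit <- if (n %% 5 == 0) 5L else 1L
  k <- n %/% unit
  q <- share * k
  base <- floor(q)
  short <- k - sum(base)
  if (short > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base * unit)
}

synthetic_foods <- function() {
  data.frame(
    item_id = c("FLOUR_COMPOSITE", "NONFLOUR_CA_FOOD", "CA_SUPPLEMENT"),
    calcium_mg_per_100g = c(0, 100, 100),
    wheat_flour_g_per_100g = c(100, 0, 0),
    is_supplement = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Generate a seeded synthetic dietary survey
#'
#' Emulates the structure a repeated-recall national survey hands to the
#' usual-intake pipeline. Per participant a latent usual calcium intake and
#' (for flour consumers) a latent usual flour intake are drawn from the
#' group's lognormal; each recalled day observes them through independent
#' multiplicative lognormal noise with the configured within-person CVs.
#' A day is realised as food records — a flour composite item whose grams
#' carry the day's flour and a non-flour item carrying the day's food
#' calcium, plus a fixed-dose supplement record for supplement users — so
#' that [person_day_totals()] reproduces the intended day totals exactly.
#' Exactly `round(replicate_fraction * n_group)` participants per group get a
#' second recall. Regions are assigned uniformly and weights set so weighted
#' region shares match the configured targets. The latent values are kept in
#' a separate `truth` table: they exist only in synthetic data and power the
#' prevalence oracles.
#'
#' @param config a [survey_config()].
#' @return A list of class `survey_dataset` with elements `participants`
#'   (id, age, sex, group, region, weight), `recalls`, `foods`, `truth`
#'   (latent usual intakes), and `config`.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  with_seed(config$seed, generate_survey_impl(config))
}

generate_survey_impl <- function(config) {
  g <- config$groups
  n_g <- allocate_groups(config$n, g$share)
  parts <- vector("list", nrow(g)); truths <- vector("list", nrow(g))
  rec1 <- vector("list", nrow(g)); rep_ids <- vector("list", nrow(g))
  next_id <- 0L
  sd_ca <- cv_to_sdlog(config$cv_calcium)
  sd_fl <- cv_to_sdlog(config$cv_flour)
  for (j in seq_len(nrow(g))) {
    n <- n_g[j]
    if (n == 0L) next
    ids <- sprintf("P%06d", next_id + seq_len(n))
    next_id <- next_id + n
    hi <- if (is.finite(g$age_hi[j])) g$age_hi[j] else 95
    age <- stats::runif(n, g$age_lo[j], hi)
    sex <- if (g$sex[j] == "ALL") sample(c("F", "M"), n, replace = TRUE)
           else rep(g$sex[j], n)
    ca_meanlog <- log(g$ca_mean[j]) - g$ca_sdlog[j]^2 / 2
    fl_meanlog <- log(g$flour_mean[j]) - g$flour_sdlog[j]^2 / 2
    ca_food <- stats::rlnorm(n, ca_meanlog, g$ca_sdlog[j])
    consumer <- stats::runif(n) < g$p_flour[j]
    flour <- ifelse(consumer, stats::rlnorm(n, fl_meanlog, g$flour_sdlog[j]), 0)
    suppl <- stats::runif(n) < config$p_supplement
    parts[[j]] <- data.frame(participant_id = ids, age = age, sex = sex,
                             group = g$group[j], stringsAsFactors = FALSE)
    truths[[j]] <- data.frame(
      participant_id = ids,
      true_usual_calcium = ca_food + ifelse(suppl, config$supplement_dose, 0),
      true_usual_flour = flour,
      supplement_user = suppl, stringsAsFactors = FALSE)
    n_rep <- round(config$replicate_fraction * n)
    rep_ids[[j]] <- if (n_rep > 0) sample(ids, n_rep) else character(0)
  }
  participants <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  truth <- do.call(rbind, truths[!vapply(truths, is.null, TRUE)])
  if (is.null(participants)) {
    participants <- data.frame(participant_id = character(0), age = numeric(0),
                               sex = character(0), group = character(0),
                               region = character(0), weight = numeric(0),
                               stringsAsFactors = FALSE)
    return(structure(list(participants = participants,
                          recalls = data.frame(participant_id = character(0),
                                               day = integer(0),
                                               item_id = character(0),
                                               grams = numeric(0)),
                          foods = synthetic_foods(),
                          truth = truth, config = config),
                     class = "survey_dataset"))
  }
  replicated <- unlist(rep_ids)

  # regions: uniform assignment, weights calibrated to target shares
  rg <- names(config$regions)
  participants$region <- sample(rg, nrow(participants), replace = TRUE)
  cnt <- table(factor(participants$region, levels = rg))
  wr <- ifelse(cnt > 0, config$regions * nrow(participants) / as.numeric(cnt), 0)
  participants$weight <- as.numeric(wr[participants$region])

  day_records <- function(day, ids) {
    i <- match(ids, truth$participant_id)
    ca_food <- truth$true_usual_calcium[i] -
      ifelse(truth$supplement_user[i], config$supplement_dose, 0)
    eps_ca <- stats::rlnorm(length(ids), -sd_ca^2 / 2, sd_ca)
    eps_fl <- stats::rlnorm(length(ids), -sd_fl^2 / 2, sd_fl)
    fl <- truth$true_usual_flour[i] * eps_fl
    ca <- ca_food * eps_ca
    recs <- rbind(
      data.frame(participant_id = ids, day = day, item_id = "FLOUR_COMPOSITE",
                 grams = fl, stringsAsFactors = FALSE),
      data.frame(participant_id = ids, day = day,
                 item_id = "NONFLOUR_CA_FOOD", grams = ca,
                 stringsAsFactors = FALSE))
    su <- ids[truth$supplement_user[i]]
    if (length(su)) {
      recs <- rbind(recs, data.frame(
        participant_id = su, day = day, item_id = "CA_SUPPLEMENT",
        grams = config$supplement_dose, stringsAsFactors = FALSE))
    }
    recs
  }
  recalls <- rbind(day_records(1L, participants$participant_id),
                   if (length(replicated)) day_records(2L, sort(replicated)))
  recalls <- recalls[order(recalls$participant_id, recalls$day,
                           recalls$item_id), ]
  rownames(recalls) <- NULL
  rownames(participants) <- NULL
  rownames(truth) <- NULL
  structure(list(participants = participants, recalls = recalls,
                 foods = synthetic_foods(), truth = truth, config = config),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("Synthetic dietary survey:", nrow(x$participants), "participants,",
      nrow(x$recalls), "recall records\n")
  n2 <- sum(table(x$recalls$participant_id[!duplicated(
    paste(x$recalls$participant_id, x$recalls$day))]) == 2)
  cat(sprintf("  two-recall participants: %d (%.1f%%)\n", n2,
              100 * n2 / max(1, nrow(x$participants))))
  cat("  groups:", length(unique(x$participants$group)),
      " regions:", length(unique(x$participants$region)), "\n")
  invisible(x)
}

#' Latent-truth prevalence oracles
#'
#' `true_prevalence()` returns the survey-weighted percentage of participants
#' whose latent usual calcium intake lies strictly below (or above) a
#' threshold; `true_prevalence_fortified()` does the same after adding
#' `level/100` mg of calcium per gram of latent usual flour, i.e. the exact
#' fortified usual intake. Both require the latent `truth` table and are
#' therefore available only for synthetic data; they serve as the reference
#' the estimation pipeline is checked against.
#'
#' @param dataset a `survey_dataset` from [generate_survey()].
#' @param threshold mg/d cut-point (an EAR or UL).
#' @param direction `"below"` or `"above"`.
#' @param level fortification level in mg calcium per 100 g wheat flour.
#' @return Weighted percentage in `[0, 100]`.
#' @export
true_prevalence <- function(dataset, threshold, direction = c("below", "above")) {
  true_prevalence_fortified(dataset, 0, threshold, direction)
}

#' @rdname true_prevalence
#' @export
true_prevalence_fortified <- function(dataset, level, threshold,
                                      direction = c("below", "above")) {
  direction <- match.arg(direction)
  stopifnot(inherits(dataset, "survey_dataset"), level >= 0)
  tr <- dataset$truth
  if (is.null(tr) || !all(c("true_usual_calcium", "true_usual_flour")
                          %in% names(tr))) {
    stop("latent usual intakes are unavailable: the truth oracle exists ",
         "only for synthetic datasets", call. = FALSE)
  }
  i <- match(dataset$participants$participant_id, tr$participant_id)
  u <- tr$true_usual_calcium[i] + tr$true_usual_flour[i] * level / 100
  w <- dataset$participants$weight
  if (direction == "below") weighted_pct_below(u, threshold, w)
  else weighted_pct_above(u, threshold, w)
}

#' Write or read a survey dataset as plain CSV files
#'
#' Writes `participants.csv`, `recalls.csv`, `foods.csv`, `truth.csv` (latent
#' values, synthetic data only) and `config.lock.json` (seed plus an MD5 of
#' the serialised config) into a directory; `read_survey()` loads them back.
#'
#' @param dataset a `survey_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_survey()` the directory, invisibly; `read_survey()` a
#'   `survey_dataset` (without `truth` if no `truth.csv` is present).
#' @export
write_survey <- function(dataset, dir) {
  stopifnot(inherits(dataset, "survey_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$recalls, file.path(dir, "recalls.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$foods, file.path(dir, "foods.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$truth)) {
    utils::write.csv(dataset$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  }
  lock <- list(seed = dataset$config$seed,
               config_md5 = config_hash(dataset$config))
  jsonlite::write_json(lock, file.path(dir, "config.lock.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(unclass(config), file = tf)
  unname(tools::md5sum(tf))
}

#' @rdname write_survey
#' @export
read_survey <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.csv")
  structure(list(
    participants = rd("participants.csv"),
    recalls = rd("recalls.csv"),
    foods = rd("foods.csv"),
    truth = if (file.exists(truth_path)) rd("truth.csv") else NULL,
    config = NULL), class = "survey_dataset")
}
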