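# Shared fixture builders. Everything is generated in code at test time.

# survey_config with a single custom group; latent usual calcium is
# lognormal(meanlog, sdlog) via the mean parameterisation
single_group_config <- function(n, seed, ca_meanlog, ca_sdlog,
                                flour_mean = 105, flour_sdlog = 0.5,
                                p_flour = 0.96, cv_calcium = 0.3,
                                cv_flour = 0.4, sex = "F",
                                age_lo = 19, age_hi = 31, ...) {
  groups <- data.frame(
    group = sprintf("%s %g-<%g", sex, age_lo, age_hi), sex = sex,
    age_lo = age_lo, age_hi = age_hi, share = 1,
    ca_mean = exp(ca_meanlog + ca_sdlog^2 / 2), ca_sdlog = ca_sdlog,
    flour_mean = flour_mean, flour_sdlog = flour_sdlog, p_flour = p_flour,
    stringsAsFactors = FALSE)
  survey_config(n = n, groups = groups, cv_calcium = cv_calcium,
                cv_flour = cv_flour, p_supplement = 0, seed = seed, ...)
}

# person-day totals with the participant's survey weight attached
totals_with_weights <- function(svy) {
  tot <- person_day_totals(svy$recalls, svy$foods)
  m <- match(tot$participant_id, svy$participants$participant_id)
  tot$weight <- svy$participants$weight[m]
  tot
}

# truth oracle restricted to one generator group
group_oracle <- function(svy, grp, level, threshold, direction) {
  keep <- svy$participants$group == grp
  sub <- svy
  sub$participants <- svy$participants[keep, ]
  sub$truth <- svy$truth[svy$truth$participant_id %in%
                           sub$participants$participant_id, ]
  true_prevalence_fortified(sub, level, threshold, direction)
}

# tiny hand-checkable foods table
tiny_foods <- function() {
  data.frame(
    item_id = c("bread", "milk", "pasta", "suppl"),
    calcium_mg_per_100g = c(120, 120, 20, 5000),
    wheat_flour_g_per_100g = c(60, 0, 70, 0),
    is_supplement = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}
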