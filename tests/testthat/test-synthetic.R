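test_that("generation is reproducible for a seed and varies across seeds", {
  cfg <- survey_config(n = 300, seed = 11)
  a <- generate_survey(cfg)
  b <- generate_survey(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$recalls, b$recalls)
  expect_identical(a$truth, b$truth)
  c <- generate_survey(survey_config(n = 300, seed = 12))
  expect_false(identical(a$recalls$grams, c$recalls$grams))
})

test_that("generator honours structural config edges", {
  expect_equal(nrow(generate_survey(survey_config(n = 0))$participants), 0L)
  expect_error(survey_config(replicate_fraction = 1.2), "replicate_fraction")
  # zero within-person CV: replicated days repeat day 1 exactly
  cfg <- single_group_config(n = 100, seed = 5, ca_meanlog = 6, ca_sdlog = 0.4,
                             cv_calcium = 0, cv_flour = 0)
  svy <- generate_survey(cfg)
  tot <- person_day_totals(svy$recalls, svy$foods)
  two <- names(which(table(tot$participant_id) == 2))
  d1 <- tot[tot$day == 1 & tot$participant_id %in% two, ]
  d2 <- tot[tot$day == 2 & tot$participant_id %in% two, ]
  expect_equal(d2$calcium[order(d2$participant_id)],
               d1$calcium[order(d1$participant_id)], tolerance = 0)
})

test_that("the second recall is assigned to exactly the design fraction", {
  svy <- generate_survey(survey_config(n = 5000, seed = 2))
  days <- table(unique(
    svy$recalls[c("participant_id", "day")])$participant_id)
  expect_identical(sum(days == 2) / nrow(svy$participants), 0.2)
})

test_that("day records reconstruct intended totals and match the latent model", {
  cfg <- single_group_config(n = 20000, seed = 31, ca_meanlog = 6.2,
                             ca_sdlog = 0.4)
  svy <- generate_survey(cfg)
  tot <- totals_with_weights(svy)
  d1 <- tot[tot$day == 1, ]
  # weighted mean day-1 calcium within 2% of the configured lognormal mean
  expect_equal(weighted_mean(d1$calcium, d1$weight), exp(6.2 + 0.4^2 / 2),
               tolerance = 0.02)
  # flour-consumer share within binomial 99% bounds of p = 0.96
  p_hat <- mean(svy$truth$true_usual_flour > 0)
  expect_lt(abs(p_hat - 0.96), 2.576 * sqrt(0.96 * 0.04 / 20000))
  # weighted region shares match configured targets by construction
  w_share <- tapply(svy$participants$weight, svy$participants$region, sum) /
    sum(svy$participants$weight)
  expect_equal(sort(as.numeric(w_share)), sort(unname(cfg$regions)),
               tolerance = 1e-12)
})

test_that("latent-truth oracles compute weighted prevalence by hand rules", {
  svy <- structure(list(
    participants = data.frame(participant_id = c("a", "b"), age = c(30, 40),
                              sex = "F", region = "R", weight = c(1, 3)),
    recalls = NULL, foods = NULL,
    truth = data.frame(participant_id = c("a", "b"),
                       true_usual_calcium = c(900, 1100),
                       true_usual_flour = c(100, 0),
                       supplement_user = FALSE)), class = "survey_dataset")
  expect_equal(true_prevalence(svy, 1000, "below"), 25)
  expect_equal(true_prevalence(svy, 1000, "above"), 75)
  # fortification moves only flour consumers: a gains 500 mg at level 500
  expect_equal(true_prevalence_fortified(svy, 500, 1000, "below"), 0)
  expect_equal(true_prevalence_fortified(svy, 0, 1000, "below"),
               true_prevalence(svy, 1000, "below"))
  svy$truth <- NULL
  expect_error(true_prevalence(svy, 1000), "latent")
})

test_that("survey round-trips through CSV files", {
  dir <- withr::local_tempdir()
  svy <- generate_survey(survey_config(n = 120, seed = 9))
  write_survey(svy, dir)
  expect_true(all(file.exists(file.path(
    dir, c("participants.csv", "recalls.csv", "foods.csv", "truth.csv",
           "config.lock.json")))))
  back <- read_survey(dir)
  expect_equal(back$participants$weight, svy$participants$weight)
  expect_equal(back$recalls$grams, svy$recalls$grams)
  expect_equal(back$truth$true_usual_calcium, svy$truth$true_usual_calcium)
})
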