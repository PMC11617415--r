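test_that("fortification arithmetic is exact and additive at the day level", {
  tot <- data.frame(participant_id = c("A", "A", "B"), day = c(1, 2, 1),
                    calcium = c(400, 500, 300), flour = c(100, 80, 0))
  expect_identical(apply_scenario(tot, 0), tot)
  f500 <- apply_scenario(tot, 500)
  expect_identical(f500$calcium, c(900, 900, 300))  # +500 at 100 g, +0 at 0 g
  expect_identical(f500$flour, tot$flour)
  expect_identical(apply_scenario(apply_scenario(tot, 200), 300),
                   apply_scenario(tot, 500))
  expect_error(apply_scenario(tot, -10), "non-negative")
})

test_that("initial gap and required level follow their defining formulas", {
  expect_equal(initial_gap(600, 1000), 400)
  expect_equal(initial_gap(1200, 1000), 0)
  expect_equal(initial_gap(550, 1100), 550)
  expect_equal(required_level(400, 100), 400)
  expect_equal(required_level(0, 80), 0)
  expect_equal(required_level(500, 50), 1000)
  expect_error(required_level(400, 0), "undefined")
})

test_that("scenario evaluation reproduces baseline and respects group structure", {
  svy <- generate_survey(survey_config(n = 4000, seed = 21))
  ad <- evaluate_scenarios(svy, levels = c(0, 200, 400, 500))
  dri <- load_dri_table()
  expect_equal(nrow(ad), nrow(dri) * 4)
  expect_true(all(ad$pct_below_ear >= 0 & ad$pct_below_ear <= 100))
  expect_true(all(ad$pct_above_ul >= 0 & ad$pct_above_ul <= 100))
  # mean usual calcium is non-decreasing in the fortification level
  for (g in unique(ad$group)) {
    a <- ad[ad$group == g, ]
    expect_true(all(diff(a$mean_calcium[order(a$level)]) >= 0))
  }
  # the baseline rows equal a direct usual-intake run on the same group
  grp <- "M 31-<51"
  tot <- totals_with_weights(svy)
  tot$group <- svy$participants$group[
    match(tot$participant_id, svy$participants$participant_id)]
  tg <- tot[tot$group == grp, ]
  fit <- usual_intake(calcium ~ participant_id, tg, weights = weight)
  ref <- lookup_dri(grp, dri)
  s <- summary(fit, ear = ref$ear_mg, ul = ref$ul_mg)
  row <- ad[ad$group == grp & ad$level == 0, ]
  expect_identical(row$mean_calcium, s$mean)
  expect_identical(row$pct_below_ear, s$pct_below_ear)
  # mean calcium gains track mean flour times the level
  for (lev in c(200, 500)) {
    rowl <- ad[ad$group == grp & ad$level == lev, ]
    gain <- rowl$mean_calcium - row$mean_calcium
    expect_equal(gain / (row$mean_flour * lev / 100), 1, tolerance = 0.05)
  }
})

test_that("the safety flag trips when UL exceedance passes the cut-off", {
  # constructed group: enough weight above the UL after fortification
  cfg <- single_group_config(n = 2000, seed = 33, ca_meanlog = 7.5,
                             ca_sdlog = 0.3, flour_mean = 150,
                             sex = "M", age_lo = 51, age_hi = 71)  # UL 2000
  svy <- generate_survey(cfg)
  ad <- suppressWarnings(
    evaluate_scenarios(svy, levels = c(0, 500), safety_cutoff = 0.5))
  high <- ad[ad$group == "M 51-<71" & ad$level == 500, ]
  expect_gt(high$pct_above_ul, 0.5)
  expect_true(high$safety_flag)
})

test_that("prevalence responds monotonically to the fortification level", {
  for (seed in c(41, 42)) {
    svy <- generate_survey(survey_config(n = 14000, seed = seed))
    ad <- evaluate_scenarios(svy, levels = c(0, 200, 400, 500))
    for (grp in unique(ad$group)) {
      a <- ad[ad$group == grp, ]
      a <- a[order(a$level), ]
      expect_true(all(diff(a$pct_below_ear) <= 0.5),
                  label = sprintf("%% below EAR non-increasing (%s, seed %d)",
                                  grp, seed))
      expect_true(all(diff(a$pct_above_ul) >= -0.5),
                  label = sprintf("%% above UL non-decreasing (%s, seed %d)",
                                  grp, seed))
    }
  }
})
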