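test_that("transform selection minimises skewness on the grid", {
  # symmetric input: identity already has zero skewness
  expect_equal(fit_transform(c(1, 2, 3))$lambda, 1)
  # lognormal input: the log transform zeroes skewness in expectation
  set.seed(101)
  x <- rlnorm(10000, 6, 0.5)
  ft <- fit_transform(x)
  expect_equal(ft$lambda, 0)
  expect_equal(ft$shift, 0)
  # zeros force a positive shift of half the smallest positive value
  ft0 <- fit_transform(c(0, x[1:50]))
  expect_equal(ft0$shift, min(x[1:50]) / 2)
  # constant input degenerates to the identity with a flag
  ftc <- fit_transform(rep(5, 20))
  expect_true(ftc$degenerate)
  expect_equal(ftc$lambda, 1)
})

test_that("variance components match the hand-worked replicate example", {
  # persons A:(1,3), B:(2,4), equal weights
  vc <- variance_components(c(1, 3, 2, 4), c("A", "A", "B", "B"))
  expect_equal(vc$var_within, 2)          # ((2^2)/2 + (2^2)/2) / 2
  expect_equal(vc$mu, 2.5)                # person means {2, 3}
  expect_equal(vc$var_between, 0)         # max(0, 0.25 - 2 * 0.5)
  expect_true(vc$truncated)
  expect_equal(vc$n_replicated, 2L)
  # identical day pairs imply zero within-person variance
  vc0 <- variance_components(c(5, 5, 7, 7, 6), c("A", "A", "B", "B", "C"))
  expect_equal(vc0$var_within, 0)
  expect_false(vc0$truncated)
  expect_error(variance_components(c(1, 2, 3), c("A", "B", "C")),
               "two recalls")
  expect_error(variance_components(c(1, 2, 3), c("A", "A", "A")), "at most 2")
})

test_that("single-recall participants enter the mean but not the within variance", {
  vc <- variance_components(c(1, 3, 2, 4, 10), c("A", "A", "B", "B", "C"))
  expect_equal(vc$var_within, 2)          # C does not touch it
  expect_equal(vc$mu, (2 + 3 + 10) / 3)
})

test_that("lognormal back-transform matches the closed form", {
  # lambda = 0: E[exp(u + sdw * Z)] = exp(u + var_w / 2)
  set.seed(55)
  df <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:20), each = 2),
    day = rep(1:2, 20),
    calcium = exp(rnorm(40, 6, 0.4)))
  fit <- usual_intake(calcium ~ participant_id, df,
                      transform = list(lambda = 0, shift = 0))
  vw <- fit$components$var_within
  vb <- fit$components$var_between
  mu <- fit$components$mu
  tx <- log(df$calcium)
  xbar <- as.numeric(
    tapply(tx, df$participant_id, mean)[fit$participants$participant_id])
  u <- mu + sqrt(vb / (vb + vw / 2)) * (xbar - mu)
  expect_equal(unname(fitted(fit)), unname(exp(u + vw / 2)),
               tolerance = 1e-6)
})

test_that("degenerate cases collapse to exact empirical quantities", {
  # no day-to-day noise + identity transform: usual equals the person mean
  df <- data.frame(
    participant_id = c("A", "A", "B", "B", "C", "D"),
    day = c(1, 2, 1, 2, 1, 1),
    calcium = c(700, 700, 900, 900, 1100, 600),
    weight = c(1, 1, 2, 2, 1, 4))
  fit <- usual_intake(calcium ~ participant_id, df, weights = weight,
                      transform = list(lambda = 1, shift = 0))
  expect_identical(fit$components$var_within, 0)
  expect_identical(unname(fitted(fit)), c(700, 900, 1100, 600))
  # complete shrinkage: zero between-variance sends everyone to mu
  df2 <- df
  df2$calcium <- c(700, 900, 800, 800, 800, 800)  # noise but equal means
  fit2 <- usual_intake(calcium ~ participant_id, df2, weights = weight,
                       transform = list(lambda = 1, shift = 0))
  expect_equal(fit2$components$var_between, 0)
  expect_equal(diff(range(fitted(fit2))), 0)
  expect_error(usual_intake(calcium ~ participant_id, df, quad_order = 2),
               "quad_order")
})

test_that("summary reports weighted cut-point prevalences and percentiles", {
  df <- data.frame(
    participant_id = c("A", "A", "B", "B"), day = c(1, 2, 1, 2),
    calcium = c(900, 900, 1100, 1100), weight = c(1, 1, 3, 3))
  fit <- usual_intake(calcium ~ participant_id, df, weights = weight,
                      transform = list(lambda = 1, shift = 0))
  s <- summary(fit, ear = 1000, ul = 1000)
  expect_equal(s$pct_below_ear, 25)       # weights {1,3} on {900,1100}
  expect_equal(s$pct_above_ul, 75)
  # ties at the threshold count as adequate and safe (strict inequalities)
  s2 <- summary(fit, ear = 900, ul = 1100)
  expect_equal(s2$pct_below_ear, 0)
  expect_equal(s2$pct_above_ul, 0)
  expect_equal(unname(weighted_quantile(c(900, 1100), c(1, 1), 0.5)), 1000)
})

test_that("estimation shrinks the distribution without moving its mean", {
  cfg <- single_group_config(n = 5000, seed = 77, ca_meanlog = 6.1,
                             ca_sdlog = 0.45, cv_calcium = 0.35)
  svy <- generate_survey(cfg)
  tot <- totals_with_weights(svy)
  fit <- usual_intake(calcium ~ participant_id, tot, weights = weight)
  p <- fit$participants
  expect_gt(fit$components$var_within, 0)
  expect_lt(weighted_var(p$usual, p$weight),
            weighted_var(p$observed_mean, p$weight))
  obs_mean <- weighted_mean(tot$calcium, tot$weight)
  expect_equal(weighted_mean(p$usual, p$weight) / obs_mean, 1,
               tolerance = 0.03)
})

test_that("predict and simulate are consistent with the fitted model", {
  cfg <- single_group_config(n = 800, seed = 15, ca_meanlog = 6.2,
                             ca_sdlog = 0.4)
  svy <- generate_survey(cfg)
  tot <- totals_with_weights(svy)
  fit <- usual_intake(calcium ~ participant_id, tot, weights = weight)
  expect_identical(unname(predict(fit, tot)), unname(fitted(fit)))
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), nrow(tot))
  expect_equal(mean(sims[[1]]$calcium) / weighted_mean(tot$calcium), 1,
               tolerance = 0.15)
  expect_identical(simulate(fit, seed = 4)[[1]], sims[[1]])
})
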