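#' Shifted Box-Cox transform and inverse
#'
#' `g(x) = ((x + shift)^lambda - 1) / lambda` for `lambda > 0` and
#' `log(x + shift)` for `lambda = 0`. The inverse clamps arguments that fall
#' outside the transform's range (and negative back-transformed intakes)
#' to 0.
#'
#' @param x intakes on the original scale (`>= 0`).
#' @param u values on the transformed scale.
#' @param lambda Box-Cox exponent in `[0, 1]`.
#' @param shift non-negative offset applied before transforming.
#' @keywords internal
box_cox <- function(x, lambda, shift = 0) {
  if (lambda == 0) log(x + shift)
  else ((x + shift)^lambda - 1) / lambda
}

#' @rdname box_cox
#' @keywords internal
box_cox_inv <- function(u, lambda, shift = 0) {
  y <- if (lambda == 0) exp(u) - shift
       else pmax(lambda * u + 1, 0)^(1 / lambda) - shift
  pmax(y, 0)
}

#' Choose a normalising transform for daily intakes
#'
#' Grid search over Box-Cox exponents `0, 0.1, ..., 1` for the one whose
#' transformed first-day intakes have weighted skewness closest to zero
#' (population-style moments, survey weights); ties go to the smaller
#' exponent, i.e. the stronger transform. The shift is 0 when all values are
#' positive, otherwise half the smallest positive value so the log end of
#' the grid stays defined. A constant input cannot be normalised: the
#' identity transform is returned with `degenerate = TRUE`.
#'
#' @param values positive daily intakes (typically day-1 values, one per
#'   participant).
#' @param weights survey weights (default equal).
#' @return List with `lambda`, `shift`, `degenerate`.
#' @export
fit_transform <- function(values, weights = NULL) {
  weights <- check_weights(values, weights)
  stopifnot(all(values >= 0))
  if (length(unique(values)) == 1L) {
    return(list(lambda = 1, shift = 0, degenerate = TRUE))
  }
  shift <- if (min(values) > 0) 0 else min(values[values > 0]) / 2
  grid <- seq(0, 1, by = 0.1)
  skew <- vapply(grid, function(l) {
    abs(weighted_skewness(box_cox(values, l, shift), weights))
  }, numeric(1))
  list(lambda = grid[which.min(skew)], shift = shift, degenerate = FALSE)
}

#' Within- and between-person variance components on the transformed scale
#'
#' From 1-2 transformed day values per participant: the within-person
#' (day-to-day) variance is the weighted mean of `(d1 - d2)^2 / 2` over
#' participants with two recalls; person means over available days give the
#' overall weighted mean `mu`, and the between-person variance is the
#' weighted variance of person means minus the within-person contribution
#' `var_within * mean(1/n_i)`, truncated at 0 (`truncated` records whether
#' truncation occurred). Participants with a single recall inform `mu` and
#' the between-person variance but not the within-person variance.
#'
#' @param value transformed person-day intakes.
#' @param participant_id participant identifier per row.
#' @param weights per-row survey weights, constant within participant
#'   (default equal).
#' @return List with `mu`, `var_between`, `var_within`, `n_replicated`,
#'   `truncated`.
#' @export
variance_components <- function(value, participant_id, weights = NULL) {
  weights <- check_weights(value, weights)
  ids <- unique(participant_id)
  i <- match(participant_id, ids)
  n_i <- tabulate(i, length(ids))
  if (any(n_i > 2)) stop("at most 2 recall days per participant", call. = FALSE)
  xbar <- as.numeric(rowsum(value, i, reorder = TRUE) / n_i)
  w_i <- as.numeric(rowsum(weights, i, reorder = TRUE) / n_i)
  rep_ids <- which(n_i == 2L)
  if (length(rep_ids) < 2L) {
    stop("need at least 2 participants with two recalls to estimate ",
         "the within-person variance", call. = FALSE)
  }
  ord <- order(i)
  vo <- value[ord]; io <- i[ord]
  d1 <- vo[!duplicated(io)]
  last <- rev(!duplicated(rev(io)))
  d2 <- vo[last]
  dd <- (d1[rep_ids] - d2[rep_ids])^2 / 2
  var_within <- sum(w_i[rep_ids] * dd) / sum(w_i[rep_ids])
  mu <- sum(w_i * xbar) / sum(w_i)
  var_means <- sum(w_i * (xbar - mu)^2) / sum(w_i)
  noise <- var_within * sum(w_i / n_i) / sum(w_i)
  var_between <- max(0, var_means - noise)
  list(mu = mu, var_between = var_between, var_within = var_within,
       n_replicated = length(rep_ids), truncated = var_means - noise < 0)
}

gauss_hermite_probabilist <- function(order) {
  gh <- pracma::gaussHermite(order)
  w <- gh$w / sum(gh$w)           # normalise: weights sum to exactly 1
  list(z = sqrt(2) * gh$x, w = w)
}

#' Fit a usual-intake distribution from repeated 24-hour recalls
#'
#' The central estimator of the package. A single 24-hour recall measures a
#' person's long-run ("usual") intake with substantial day-to-day error;
#' comparing one-day intakes with an EAR therefore overstates the spread of
#' the distribution and biases prevalence estimates at both tails. This
#' function removes the day-to-day component with a classical
#' measurement-error model in four steps: (1) choose a shifted Box-Cox
#' transform that symmetrises the day-1 intake distribution
#' ([fit_transform()]); (2) estimate within- and between-person variance
#' components on the transformed scale from the replicate recalls
#' ([variance_components()]); (3) shrink each person's transformed mean
#' towards the group mean by `sqrt(var_b / (var_b + var_w / n_i))` so
#' person-level values have usual-intake rather than day-level spread;
#' (4) back-transform with Gauss-Hermite quadrature over the within-person
#' distribution, `U_i = sum_k w_k g^{-1}(u_i + z_k * sd_w)`, the person's
#' expected daily intake on the original scale.
#'
#' @param formula one-sided model description `intake ~ participant`,
#'   naming the day-total column and the participant identifier in `data`.
#' @param data data frame of person-day totals (e.g. from
#'   [person_day_totals()]); one row per recalled day, at most two per
#'   participant.
#' @param weights survey weights, evaluated in `data` (constant within
#'   participant). Default equal weights.
#' @param day optional name of the recall-day column; day-1 rows drive the
#'   transform fit. If absent, each participant's first row is taken as
#'   day 1.
#' @param transform optionally a fixed `list(lambda, shift)` to bypass the
#'   grid search.
#' @param quad_order Gauss-Hermite order (default 21, must be `>= 3`).
#' @return An object of class `usual_intake`: a list with `transform`,
#'   `components`, and a `participants` data frame carrying each person's
#'   number of recall days, observed mean daily intake, and estimated usual
#'   intake, plus the survey weight. Methods: [print()], [summary()]
#'   (weighted mean, percentiles and EAR/UL prevalence), [coef()],
#'   [fitted()], [predict()], [residuals()], [simulate()], [plot()].
#' @examples
#' cfg <- survey_config(n = 500, seed = 7)
#' svy <- generate_survey(cfg)
#' totals <- person_day_totals(svy$recalls, svy$foods)
#' totals$weight <- svy$participants$weight[
#'   match(totals$participant_id, svy$participants$participant_id)]
#' fit <- usual_intake(calcium ~ participant_id, totals, weights = weight)
#' summary(fit, ear = 800, ul = 2500)
#' @export
usual_intake <- function(formula, data, weights = NULL, day = "day",
                         transform = NULL, quad_order = 21) {
  cl <- match.call()
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  value_var <- all.vars(formula[[2]])
  id_var <- all.vars(formula[[3]])
  stopifnot(length(value_var) == 1L, length(id_var) == 1L)
  x <- data[[value_var]]
  id <- data[[id_var]]
  if (is.null(x) || is.null(id)) {
    stop("formula variables not found in data", call. = FALSE)
  }
  if (any(x < 0) || anyNA(x)) stop("intakes must be non-negative", call. = FALSE)
  w <- eval(substitute(weights), data, parent.frame())
  w <- check_weights(x, w)
  bad <- tapply(w, id, function(v) diff(range(v)) > 0)
  if (any(bad)) stop("weights must be constant within participant", call. = FALSE)
  if (quad_order < 3) stop("quad_order must be at least 3", call. = FALSE)

  dy <- if (day %in% names(data)) data[[day]] else stats::ave(
    seq_along(id), id, FUN = seq_along)
  o <- order(match(id, unique(id)), dy)
  first <- o[!duplicated(id[o])]   # earliest recall day per participant
  if (is.null(transform)) {
    transform <- fit_transform(x[first], w[first])
  } else {
    transform <- list(lambda = transform$lambda,
                      shift = if (is.null(transform$shift)) 0 else transform$shift,
                      degenerate = FALSE)
  }
  tx <- box_cox(x, transform$lambda, transform$shift)
  comps <- variance_components(tx, id, w)

  ids <- unique(id)
  i <- match(id, ids)
  n_i <- tabulate(i, length(ids))
  xbar_t <- as.numeric(rowsum(tx, i, reorder = TRUE) / n_i)
  xbar_o <- as.numeric(rowsum(x, i, reorder = TRUE) / n_i)
  w_i <- as.numeric(rowsum(w, i, reorder = TRUE) / n_i)

  usual <- back_transform_usual(xbar_t, n_i, transform, comps, quad_order)

  structure(list(
    call = cl, transform = transform, components = comps,
    quad_order = quad_order,
    participants = data.frame(
      participant_id = ids, n_days = n_i, observed_mean = xbar_o,
      usual = usual, weight = w_i, stringsAsFactors = FALSE),
    value_var = value_var, id_var = id_var),
    class = "usual_intake")
}

# shrinkage + Gauss-Hermite back-transform of transformed person means
back_transform_usual <- function(xbar_t, n_i, transform, comps, quad_order) {
  vb <- comps$var_between; vw <- comps$var_within
  c_i <- if (vb == 0) rep(0, length(xbar_t))
         else sqrt(vb / (vb + vw / n_i))
  u <- ifelse(c_i == 1, xbar_t, comps$mu + c_i * (xbar_t - comps$mu))
  if (vw == 0) {
    return(box_cox_inv(u, transform$lambda, transform$shift))
  }
  gh <- gauss_hermite_probabilist(quad_order)
  sdw <- sqrt(vw)
  U <- numeric(length(u))
  for (k in seq_along(gh$z)) {
    U <- U + gh$w[k] *
      box_cox_inv(u + gh$z[k] * sdw, transform$lambda, transform$shift)
  }
  pmax(U, 0)
}

#' @export
print.usual_intake <- function(x, digits = 4, ...) {
  cat("Usual-intake fit (", x$value_var, " by ", x$id_var, ")\n", sep = "")
  cat(sprintf("  participants: %d (%d with 2 recalls)\n",
              nrow(x$participants), x$components$n_replicated))
  cat(sprintf("  transform: Box-Cox lambda = %g, shift = %g%s\n",
              x$transform$lambda, x$transform$shift,
              if (isTRUE(x$transform$degenerate)) " [degenerate input]" else ""))
  cat(sprintf("  transformed scale: mu = %.*g, var_between = %.*g, var_within = %.*g%s\n",
              digits, x$components$mu, digits, x$components$var_between,
              digits, x$components$var_within,
              if (isTRUE(x$components$truncated)) " [truncated at 0]" else ""))
  cat(sprintf("  weighted mean usual intake: %.*g\n", digits,
              weighted_mean(x$participants$usual, x$participants$weight)))
  invisible(x)
}

#' @export
coef.usual_intake <- function(object, ...) {
  c(lambda = object$transform$lambda, shift = object$transform$shift,
    mu = object$components$mu, var_between = object$components$var_between,
    var_within = object$components$var_within)
}

#' @export
fitted.usual_intake <- function(object, ...) {
  stats::setNames(object$participants$usual, object$participants$participant_id)
}

#' @export
residuals.usual_intake <- function(object, ...) {
  # transformed-scale day deviations are not stored; expose the shrinkage
  # residual instead: observed person mean minus usual intake
  object$participants$observed_mean - object$participants$usual
}

#' Summarise a usual-intake distribution
#'
#' Survey-weighted mean, percentiles, and — when reference values are
#' supplied — the prevalence of inadequacy (% of weight with usual intake
#' strictly below the EAR) and risk of excess (% strictly above the UL),
#' the cut-point method for both tails.
#'
#' @param object a [usual_intake()] fit.
#' @param ear,ul optional reference values in mg/d.
#' @param probs percentile probabilities.
#' @param ... unused.
#' @return A list of class `summary.usual_intake` with `n`, `mean`,
#'   `quantiles`, `pct_below_ear`, `pct_above_ul`, and the transform /
#'   variance-component parameters.
#' @export
summary.usual_intake <- function(object, ear = NULL, ul = NULL,
                                 probs = c(0.05, 0.1, 0.25, 0.5, 0.75,
                                           0.9, 0.95), ...) {
  u <- object$participants$usual
  w <- object$participants$weight
  out <- list(
    n = length(u),
    mean = weighted_mean(u, w),
    quantiles = weighted_quantile(u, w, probs),
    pct_below_ear = if (is.null(ear)) NULL else weighted_pct_below(u, ear, w),
    pct_above_ul = if (is.null(ul)) NULL else weighted_pct_above(u, ul, w),
    ear = ear, ul = ul,
    transform = object$transform, components = object$components)
  class(out) <- "summary.usual_intake"
  out
}

#' @export
print.summary.usual_intake <- function(x, digits = 4, ...) {
  cat("Usual-intake distribution (survey-weighted)\n")
  cat(sprintf("  n = %d, mean = %.*g\n", x$n, digits, x$mean))
  print(round(x$quantiles, 1))
  if (!is.null(x$pct_below_ear)) {
    cat(sprintf("  %% below EAR (%g): %.1f\n", x$ear, x$pct_below_ear))
  }
  if (!is.null(x$pct_above_ul)) {
    cat(sprintf("  %% above UL (%g): %.1f\n", x$ul, x$pct_above_ul))
  }
  invisible(x)
}

#' Predict usual intakes for new person-day totals
#'
#' Applies the fitted transform, shrinkage and back-transform to new
#' person-day data without re-estimating any parameter.
#'
#' @param object a [usual_intake()] fit.
#' @param newdata data frame with the same intake and id columns the model
#'   was fitted with.
#' @param ... unused.
#' @return Named vector of usual intakes (mg/d), one per participant in
#'   `newdata`.
#' @export
predict.usual_intake <- function(object, newdata, ...) {
  if (missing(newdata)) return(fitted(object))
  x <- newdata[[object$value_var]]
  id <- newdata[[object$id_var]]
  stopifnot(!is.null(x), !is.null(id), all(x >= 0))
  tx <- box_cox(x, object$transform$lambda, object$transform$shift)
  ids <- unique(id)
  i <- match(id, ids)
  n_i <- tabulate(i, length(ids))
  xbar_t <- as.numeric(rowsum(tx, i, reorder = TRUE) / n_i)
  stats::setNames(
    back_transform_usual(xbar_t, n_i, object$transform, object$components,
                         object$quad_order),
    ids)
}

#' Simulate person-day intakes from a fitted usual-intake model
#'
#' Draws new transformed person effects `N(mu, var_between)` and day noise
#' `N(0, var_within)`, back-transforms, and returns person-day tables with
#' the fitted participants' recall design (same number of days and weights).
#'
#' @param object a [usual_intake()] fit.
#' @param nsim number of datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of `nsim` data frames with columns `participant_id`,
#'   `day`, the intake column (named as fitted), and `weight`.
#' @export
simulate.usual_intake <- function(object, nsim = 1, seed = NULL, ...) {
  run <- function() {
    lapply(seq_len(nsim), function(s) {
      p <- object$participants
      rows <- rep(seq_len(nrow(p)), p$n_days)
      b <- stats::rnorm(nrow(p), object$components$mu,
                        sqrt(object$components$var_between))
      e <- stats::rnorm(length(rows), 0, sqrt(object$components$var_within))
      val <- box_cox_inv(b[rows] + e, object$transform$lambda,
                         object$transform$shift)
      out <- data.frame(participant_id = p$participant_id[rows],
                        day = stats::ave(rows, rows, FUN = seq_along),
                        value = val, weight = p$weight[rows],
                        stringsAsFactors = FALSE)
      names(out)[names(out) == "value"] <- object$value_var
      out
    })
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
plot.usual_intake <- function(x, main = "Observed vs usual intake", ...) {
  p <- x$participants
  d_obs <- suppressWarnings(
    stats::density(p$observed_mean, weights = p$weight / sum(p$weight)))
  d_usual <- suppressWarnings(
    stats::density(p$usual, weights = p$weight / sum(p$weight)))
  graphics::plot(d_obs, col = "grey50", lty = 2, main = main,
                 xlab = x$value_var, ylim = range(0, d_obs$y, d_usual$y), ...)
  graphics::lines(d_usual, col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = c("observed person means", "usual"),
                   col = c("grey50", "firebrick"), lty = c(2, 1), bty = "n")
  invisible(x)
}
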