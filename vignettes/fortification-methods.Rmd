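---
title: "Methods: usual calcium intake and flour-fortification simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: usual calcium intake and flour-fortification simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fortisim)
```

## The estimation problem

A 24-hour recall is an unbiased but noisy measure of a person's usual daily
intake: day-to-day variation within a person is typically as large as the
variation between people. The quantity public-health decisions need is the
*usual-intake distribution* of a group — the distribution of long-run
person means — because prevalence of inadequacy is defined by the cut-point
method as the share of that distribution below the group's estimated
average requirement (EAR), and risk of excess as the share above the
tolerable upper intake level (UL). Feeding one-day intakes into those
cut-points overstates both tails.

`usual_intake()` implements a transform–components–shrinkage–back-transform
estimator in the tradition of the national-survey intake-modelling programs
(the "adjust a one-day distribution using replicate recalls" family). The
original programs' internals are not fully published; this package
re-specifies the variant it uses completely, so every number it produces is
reproducible from the code:

1. **Transform** daily intakes with a shifted Box–Cox,
   $g(x) = ((x+s)^\lambda - 1)/\lambda$ ($\log(x+s)$ at $\lambda = 0$).
   $\lambda$ is chosen from the grid $\{0, 0.1, \dots, 1\}$ to minimise the
   absolute survey-weighted skewness of day-1 intakes; ties prefer the
   smaller $\lambda$ (the stronger transform). The grid is deliberately
   coarse: skewness is estimated with sampling error, and neighbouring
   $\lambda$ values are practically indistinguishable after
   back-transformation.
2. **Variance components** on the transformed scale. With one or two days
   per person, the within-person variance is identified by the replicate
   subsample: $\hat\sigma^2_w$ is the weighted mean of $(x_{i1}-x_{i2})^2/2$.
   The between-person variance subtracts the noise left in person means,
   $\hat\sigma^2_b = \max\!\big(0,\ \widehat{\mathrm{Var}}(\bar x_i) -
   \hat\sigma^2_w \,\overline{1/n_i}\big)$, truncating at zero (with a
   recorded flag) rather than failing — small groups with weak replication
   can produce a negative raw estimate.
3. **Shrinkage.** Person means are pulled toward the group mean by
   $c_i = \sqrt{\sigma^2_b/(\sigma^2_b + \sigma^2_w/n_i)}$, the factor that
   gives the shrunken values the between-person (usual) variance. When both
   components are zero, $c_i = 0$.
4. **Back-transformation.** The usual intake on the original scale is the
   expected daily intake, $U_i = \sum_k \omega_k\, g^{-1}(u_i + z_k
   \sigma_w)$, integrating over the within-person distribution with
   Gauss–Hermite quadrature rather than inverting at the mean — inverting
   a nonlinear transform at the mean would bias group means downward.

Model assumptions worth stating: on the transformed scale intake is additive
with homoscedastic within-person noise; the two recall days are independent
given the person; there are no systematic day-of-week, season or recall-order
effects (the generator produces none, and none are modelled); and calcium is
consumed daily, so no zero-inflation / episodic two-part structure is
needed.

## Tunable parameters

* `quad_order` (default 21). Gauss–Hermite order for the back-transform.
  The integrand $e^{\sigma_w z}$ (at $\lambda = 0$) is entire, so accuracy
  is limited only by order; 21 nodes reproduce the lognormal closed form
  $\exp(u + \sigma^2_w/2)$ to better than $10^{-6}$ relative at the
  within-person variances recall data produce. Orders below 3 are rejected.
  Weights are normalised to sum to exactly 1 so a zero-variance fit is an
  identity.
* `transform` (default: fitted). Can be fixed, e.g.
  `list(lambda = 1, shift = 0)`, to bypass the grid — used when day totals
  are already symmetric or for exactness checks.
* `levels` (default 0/200/400/500 mg calcium per 100 g flour). The
  candidate fortification levels; 0 is always evaluated as the baseline
  that anchors reductions and the initial gap.
* `safety_cutoff` (default 0.5%). A scenario is flagged (not rejected) when
  the group's share above the UL exceeds this percentage.
* DRI tables. Shipped as editable CSVs; the default grid uses half-open
  age intervals `[lo, hi)` — "9 to less than 14" generalised to every
  boundary — with sex-pooled groups below age 9 and a 71+ open group.
  A second variant (`"efsa_ul"`) raises the adult UL to 2500 mg/d, the
  EFSA panel position for older adults, for sensitivity analyses; with it,
  higher fortification levels pass the safety cut-off in older men.
  Infants under 1 year are excluded from the defaults: their group
  boundaries and reference values are not well standardised and the
  analyses this package targets start at age 1.
* `gap_stat` (default `"mean"`). The initial gap is
  $\max(0, \mathrm{EAR} - \text{mean usual intake})$; the median is
  available by configuration since "the usual intake of the group" is
  ambiguous between the two. The mean keeps the gap consistent with
  `required_level()`, which divides by mean flour.

## The synthetic generator

`generate_survey()` emulates the *statistical structure* the estimator
relies on, with defaults chosen to look like an urban Argentine nutrition
survey: 14 age–sex groups; usual calcium lognormal with group means
400–600 mg/d (SD on the log scale 0.45, a typical day-level spread for a
single nutrient); usual flour lognormal with group means 55–110 g/d
(highest in men 19–<51, lowest in women 51+); 96% flour consumers; 0.1%
calcium-supplement users at 500 mg/d; within-person CVs 0.35 (calcium) and
0.45 (flour), the range replicate-recall studies report for dairy-driven
nutrients; a repeated recall on 20% of each group; and six regions whose
weighted shares are matched exactly by construction of the weights.

Choices that make the design exactly reproducible: replicate selection is an
exact count, `round(0.2 * n_group)`, rather than Bernoulli; and group sample
sizes are apportioned in multiples of 5 (largest-remainder on `n/5`), so
whenever the total is a multiple of 5 the overall two-recall share is
*exactly* 20%. Each recalled day is realised as actual food records — a
flour-composite item whose grams carry the day's flour and a separate item
carrying the day's calcium — so the aggregation code path is exercised, not
bypassed; the flour composite carries no intrinsic calcium, keeping the two
day-level noises independent by construction.

What the generator does **not** emulate: multistage cluster sampling
(weights are generated directly, so design-effect and variance-estimation
behaviour is untested), correlation between calcium and flour within person,
food-item heterogeneity (two synthetic items stand for a whole composition
table), intake reporting error beyond day-to-day noise (no under-reporting),
and seasonal or weekday structure. Passing tests therefore demonstrate
correctness of the estimation and simulation machinery under the stated
model, not robustness to the many ways real recall data violate it.

Latent usual intakes are stored in a separate `truth` table and power two
oracles, `true_prevalence()` and `true_prevalence_fortified()`, which give
the exact weighted prevalence implied by the generator — the reference
against which estimated prevalences are bounded (within 4 percentage points
in the default test configurations).

## Numerical choices and degenerate inputs

* Weighted moments use the population convention (denominator $\sum w$);
  percentiles interpolate the weighted empirical CDF at plotting positions
  $(\mathrm{cum}\,w - w/2)/\sum w$ and clamp to the observed extremes.
* Strict inequalities at both cut-points: a usual intake exactly at the EAR
  counts as adequate, exactly at the UL as safe.
* Threshold proportions are clamped to $[0, 100]$: partial weight sums can
  exceed the total by an ulp under floating-point addition.
* Zeros in intakes: the Box–Cox shift is half the smallest positive value;
  back-transforms that land below zero clamp to 0.
* A constant intake vector cannot be normalised; the transform degenerates
  to the identity with a flag rather than an error.
* `apply_scenario()` is exact per record, so scenario application is
  associative (`a` then `b` equals `a + b`) and level 0 is a bit-identical
  no-op; baseline summary rows match a direct fit bit for bit.
* Person-day aggregation sorts records into a canonical order before
  summation, making totals bit-stable under permutation of the input file.
* Shrinkage with $c_i = 1$ (no within-person variance) short-circuits to
  the person mean itself, avoiding the one-ulp drift of
  $\mu + (\bar x_i - \mu)$, so the zero-noise case is *exactly* the
  empirical weighted proportion.

## Open design decisions

* **Per-group estimation.** Transform and variance components are estimated
  separately within each age–sex group (not pooled): requirement groups
  differ in both level and day-to-day spread, and pooling would leak
  between-group variance into $\sigma^2_b$.
* **Re-fit per scenario.** Fortified totals get a fresh transform and fresh
  components rather than a shifted baseline distribution; adding a
  flour-proportional amount changes skewness, and re-fitting mirrors how
  the survey programs would be re-run on fortified data. The cost is a
  sub-tolerance wiggle (< 0.5 pp) in monotonicity across levels when the
  selected $\lambda$ changes between scenarios.
* **Supplements** enter the daily calcium total like any food (they are
  part of reported intake), contribute zero flour, and are flagged so
  reports can count users; they are not modelled as a separate component
  before adjustment.
* **Single combined daily total.** Food and supplement calcium are adjusted
  together; at the < 0.1% supplement-user rates modelled here a two-part
  treatment would change nothing.

## Problem sizes

The test-suite and acceptance-script configurations are sized for tight
statistical bounds at interactive runtimes: 30 000 participants
(≈ 2 100 per group) for oracle-agreement checks, 14 000 for monotonicity
across levels, 30 replicate surveys of 2 000 for parameter recovery against
the analytic lognormal prevalence, and 20 000 in one group for generator
calibration. These sizes are the package's own choice of precision/runtime
trade-off; estimates at national-survey scale (≈ 20 000 participants) run
in seconds.

## Limitations

Uncertainty intervals around prevalence are not produced (no bootstrap or
design-based variance); the estimator targets the population distribution,
not individual intakes — $U_i$ is a shrunken expectation, not a personal
diagnosis; groups with fewer than two replicated participants cannot be
estimated; and all safety conclusions inherit the UL tables' own
uncertainty, which is why the 2500 mg/d variant ships alongside the
default.
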