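---
title: "Methods: propensity-matched analysis of HOLC grades and birth outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propensity-matched analysis of HOLC grades and birth outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Home Owners' Loan Corporation (HOLC) "Security Maps" from the 1930s graded
urban neighborhoods A ("Best") through D ("Hazardous", the origin of
*redlining*). The question this package addresses is whether births occurring
decades later in worse-graded neighborhoods have higher odds of adverse
perinatal outcomes — preterm birth, low birth weight (LBW),
small-for-gestational-age (SGA), and perinatal mortality, plus the secondary
outcomes very preterm, very low birth weight and neonatal mortality — once
the neighborhood conditions that *preceded* grading are accounted for.

Contemporary neighborhood measures are plausible mediators of any grade
effect, so adjustment uses 1940 census tract measures instead: counts of
White, non-White, foreign-born White, Black and employed residents, home
counts with radio / refrigerator / heating / major-repair splits, education
counts, persons per housing unit, median home value, and population density.
Because grade A neighborhoods have essentially no propensity of having been
graded C or D (a positivity violation), estimation is restricted to the three
adjacent contrasts B vs A, C vs B and D vs C.

The pipeline is:

1. **Spatial assignment** — each birth's planar coordinates are matched to a
   HOLC polygon (point-in-polygon); births inside a metro's map boundary but
   in no graded polygon are "NG", births outside any boundary are excluded.
2. **Areal apportionment** — 1940 tract metrics are transferred to HOLC
   polygons with weights `intersection area / HOLC polygon area`.
3. **Outcome coding** — seven binary outcomes from gestational days, grams,
   sex and death timing.
4. **Propensity scores** — per contrast, the probability that a neighborhood
   received the worse grade given all 1940 covariates, estimated by a
   cross-validated stacked ensemble.
5. **Support trimming and full matching** — 1st/99th percentile support
   restriction, then optimal full matching under a propensity caliper with a
   Mahalanobis within-caliper distance; neighborhood weights propagate to
   births.
6. **Inference** — weighted balance t-tests and weighted adjusted logistic
   models with cluster-robust confidence intervals.

`holc_fit()` runs stages 4–6 for one contrast and returns a model object
with the usual `print`/`summary`/`coef`/`confint`/`predict`/`plot` methods;
`run_full_analysis()` iterates contrasts, outcomes and strata.

## Areal apportionment

For HOLC polygon $h$ and tract $t$, the weight is
$w_{ht} = |h \cap t| / |h|$: the *target* polygon's area is the denominator,
so a polygon fully covered by tracts has weights summing to one. Every
metric — counts, median home value, and tract population density alike — is
apportioned as $\sum_t w_{ht} m_t$. This is deliberate: classical dasymetric
interpolation would scale counts by the share of the *source* tract instead;
the uniform target-share rule is the one this analysis defines, and it is
applied to all metrics uniformly rather than special-casing the median.
Derived rates (percent non-White, percent radio ownership, ...) are ratios
of weighted numerators to weighted denominators, which makes them invariant
to partial coverage. When weights sum to less than one the values are *not*
renormalised; the coverage fraction is reported per polygon so users can
screen. Intersections below $10^{-10}$ of the polygon area are dropped as
floating-point slivers.

Geometry is planar in arbitrary units with no projection handling — every
step of the method is projection-invariant, and the synthetic city uses
rectangle tessellations where intersection areas are exactly computable. The
polygon primitives (shoelace areas, ray-cast containment with boundary
detection, clipping against ear-clipped triangles) are implemented in the
package and validated against exact rectangle arithmetic; they handle
general simple polygons with holes, which is sufficient for digitised map
input.

## The propensity ensemble

Five learner families are stacked: a grand-mean model; linear-logistic
regression; ridge-penalised logistic regression (a deterministic stand-in
for a weakly-informative-prior Bayesian GLM); an adaptive piecewise-linear
hinge-spline logistic model grown by forward selection at tercile knots
(playing the multivariate-adaptive-spline role); and a penalised additive
natural-spline logistic model (3 df per covariate, ridge penalty, the
generalised-additive-model role). Out-of-fold predictions from `k` stratified
folds (default 10; fold assignment is seed-controlled) feed a non-negative
stacking weight vector on the simplex chosen to minimise cross-validated
log-loss. Final propensities are the stack of refit learners, clipped to
$[10^{-6}, 1-10^{-6}]$.

Support trimming removes neighborhoods with propensity below the 1st
percentile of the better-graded arm or above the 99th percentile of the
worse-graded arm (linear-interpolation quantiles), the window within which
comparison does not extrapolate.

## Optimal full matching as minimum-cost edge cover

A full match partitions on-support neighborhoods into subclasses of one
treated with $\ge 1$ controls or one control with $\ge 2$ treated. Pairs are
admissible when their propensity difference is at most 0.2 standard
deviations of the propensity in the contrast sample (on the raw propensity
scale — the definition names no transformation), and pair distance is the
Mahalanobis distance on percent non-White and median home value, with
covariance pooled over the on-support sample plus a $10^{-8}$ ridge.

With non-negative distances, the optimal full match is exactly the
minimum-cost edge cover of the admissible bipartite graph. The package
solves it by the classical exact reduction: subtract each vertex's cheapest
incident edge cost, find the minimum-cost matching over the negative
reduced-cost edges (successive shortest augmenting paths, stopping when the
best path is non-negative), then cover every remaining vertex with its
cheapest edge and remove redundant edges (most expensive first) until every
component is a star. Units with no admissible partner are discarded and
logged. Weights follow the subclassification rule: each matched treated
neighborhood has weight 1; each control receives its subclass's ratio of
treated to control counts. Births inherit their neighborhood's weight, with
zero for trimmed, unmatched, NG and outside-map births. The solver is
verified against exhaustive enumeration on all instances with up to 4+4
units in the test suite.

## Outcome models and uncertainty

Each contrast/outcome cell is a weighted logistic regression of the outcome
on the worse-grade indicator plus four areal-weighted 1940 covariates:
median home value, percent employed, percent radio ownership and percent
non-White (the remaining covariates are near-collinear with these; a
Spearman screen with a 0.7 flag threshold is reported as a diagnostic but
does not alter the fixed covariate set). Weights are rescaled to mean one
among included births, which stabilises the weighted-GLM scale without
changing point estimates. The sensitivity variant appends maternal age,
parity and birth year.

Births sharing a neighborhood share exposure, covariates and weight, so
model-based standard errors are anticonservative. Confidence intervals
therefore use a cluster-robust sandwich clustered on neighborhood with a
jackknife-type small-sample leverage adjustment: CR3 cluster blocks
$(I-H_{cc})^{-1}$ applied to the working residuals, with
Satterthwaite–Imbens–Kolesár degrees of freedom and t quantiles. Full
matching concentrates weight on few neighborhoods (a control matched to $m$
treated carries weight $m$), so the effective number of clusters is small
and unbalanced — the regime in which the plain CR0 sandwich and, more
mildly, the Bell–McCaffrey CR2 form are anticonservative while jackknife
scaling restores validity, the ordering the few-cluster literature
predicts. The test suite verifies null calibration of the default over
replicated synthetic studies. CR3 errs on the conservative side where
clusters are plentiful; the CR2 form and model-based Wald intervals remain
available (`robust = FALSE` for the latter). No multiplicity adjustment
is applied; the analysis object records the number of tests performed.

Balance is reported as treated-minus-control mean differences of seven 1940
covariates before matching (unweighted) and after (matching weights), using
a weighted Welch t-test with effective sample sizes
$n_\mathrm{eff} = (\sum w)^2 / \sum w^2$ and Welch–Satterthwaite degrees of
freedom; with unit weights it reduces exactly to the classical Welch test.

## The synthetic study

Real inputs (statewide birth records, digitised HOLC shapefiles, 1940
census extracts) are respectively confidential or external downloads, so the
package ships a generator that emulates the study's structure end to end and
makes every stage testable with known truth.

**City.** An `n_cols x n_rows` grid of unit cells forms the HOLC layer;
grades are drawn from a configurable frequency vector (default
A/B/C/D/NG = .10/.20/.35/.30/.05) with neighbour-copy smoothing (default
probability 0.3) that clusters grades spatially while leaving the marginal
distribution unchanged. A second grid, offset by a configurable fraction of
a cell (default 0.4; offsets of exactly zero or one cell are rejected as a
degenerate overlay), plays the 1940 tracts, so every interior polygon is
genuinely split across tracts. Two metro labels split the grid columns
(default 75% "LA") and each metro carries an explicit map-boundary polygon,
which is what makes the NG / outside distinction well defined.

**Tract metrics.** Each tract's generating profile is the area-weighted mix
of per-grade profiles chosen to move in the directions of the observed
pre-match differences (worse grades: lower median home value, more residents
of color, more homes needing repairs, lower radio ownership, denser
occupancy). Totals are gamma draws (CV 0.3) and splits are binomial, so
subcounts respect totals by construction. Census rates vary far more between
real tracts than binomial noise allows, so each profile rate receives a
logit-scale jitter (SD 0.9) before the binomial split; without this
overdispersion the arms become almost perfectly separable in propensity and
the positivity regime the method presumes never arises.

**Births.** Locations are uniform within a polygon chosen proportionally to
per-grade intensity times area; configurable fractions fall outside the map
(2%) or below 24 weeks' gestation (0.4%) to exercise the inclusion flow.
Outcome indicators come first, from logistic models
$\mathrm{logit}\,P = \alpha_o + \theta_{g,o} + \gamma^\top (x - \bar x) +
\text{maternal terms}$, where $\theta$ accumulates the configured
adjacent-contrast conditional log-odds along A→B→C→D and $x$ are the
polygon's areal-weighted metrics (defaults: $-0.04$ per \$1000 of median
home value and $+0.012$ per point of percent non-White, for all outcomes —
so crude contrasts are genuinely confounded). Each outcome indicator is
generated from its own logistic model (the secondary outcomes very preterm,
VLBW and neonatal mortality conditionally within their parent outcome, which
preserves the implication lattice). Gestational days and grams are then
drawn *conditionally on* the indicators (weight mean increasing in
gestational age within each weight class, male shift +110 g), so downstream
coding recovers the generated indicators exactly. The exception is SGA,
which has no generating indicator of its own: it is
injected as a standardised downward birth-weight shift of
$\mathrm{lp}/1.95$ SDs (1.95 is the derivative of the logit of the lower
tail probability at the 10th percentile of a normal), an approximation that
is exact at the null. Maternal covariates (race, education, payer, age,
parity) follow grade-dependent distributions so descriptive tables show
realistic gradients, but their outcome coefficients default to zero: the
study design treats them as markers, and whether they confound or mediate
is left to the user's configuration rather than fixed by the generator.

**What passing tests do and do not show.** The generator produces polygon
tessellations with exact geometry, independent tracts given grade, logistic
outcome mechanisms and outcome-independent exclusions. Real data have
irregular digitised polygons, spatially correlated census errors,
non-logistic risk surfaces and address-geocoding failure that may correlate
with outcomes. Parameter recovery here demonstrates that the *estimator* is
implemented correctly, not that the design is unconfounded in real use.

## Numerical and design choices

* Gestational age is modelled in days (preterm < 259, very preterm < 224,
  coding refuses records below 168); weeks are `days %/% 7`.
* LBW/VLBW thresholds are strict (`< 2500`, `< 1500` g); SGA is strict
  (`<` the sex-week 10th percentile); "within the first 28 days" is
  `death_age_days < 28`; perinatal mortality counts any non-elective
  recorded death without an upper age bound, the literal reading of the
  definition.
* The SGA reference is the empirical sex-week 10th percentile
  (linear-interpolation quantile), isotonically adjusted and then forced
  strictly increasing across weeks; cells under 100 births are unsupported
  and code SGA as missing. A loader accepts any user-supplied
  (sex, week, p10) CSV; a synthetic example table ships in `extdata`.
* Boundary birth locations are assigned to the lexicographically smallest
  containing `polygon_id` — deterministic and order-independent.
* The exclusion order is fixed: outside map, then gestation < 24 weeks,
  then unknown outcome fields (last, so flow counts are outcome-set
  specific). NG births are retained for descriptive tables but ineligible
  for contrasts.
* Stacking weights are optimised through a softmax parameterisation with
  BFGS; learner-internal penalties use deterministic fold assignments, so a
  fixed seed reproduces every table byte-identically.
* Caliper admissibility is decided first, then Mahalanobis cost optimised
  within the admissible graph.
* All simulation sizes in the test suite are stated choices of this
  package: the calibration and balance suites use a 200-neighborhood city
  with 40,000 births per replicate over 100 seeds; parameter recovery uses
  200 neighborhoods and 100,000 births over 50 seeds with an injected
  D-vs-C preterm odds ratio of 0.93; ensemble folds are 5 in these suites
  and 10 by default.

## Known limitations

* The simplex stacking optimiser can place weight on a flat ridge when two
  learners make identical predictions; the propensities are unaffected.
* The minimum-cost matching solver is exact but dense
  (O(arms²) per augmentation); it is comfortable at the hundreds of
  neighborhoods this design uses, not at tens of thousands.
* With birth-level covariates in the sensitivity model the CR2 adjustment
  still treats the neighborhood as the cluster; maternal covariates that
  vary within neighborhoods make that adjustment heavier than necessary but
  not invalid.
* SGA effect injection is first-order accurate in the injected log-odds;
  large injected SGA effects (|log OR| > ~0.3) will be attenuated.
* The unknown-covariate descriptive level ("unknown" education) is kept in
  tables and dropped from regressions, mirroring the complete-case design;
  no imputation is implemented.
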