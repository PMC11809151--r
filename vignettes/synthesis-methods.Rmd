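---
title: "Sequential synthesis and disclosure-controlled release of cohort data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential synthesis and disclosure-controlled release of cohort data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortsynth)
```

Restricted cohort studies cannot publish participant-level data, yet open
science increasingly expects data alongside papers. A practical compromise is
a *wholly synthetic* dataset: modelled on the observed records so that
marginal distributions and relations between variables are approximately
preserved, but corresponding to no real individual. This vignette describes
the models and procedures this package implements, the choices we made where
the design was genuinely open, and what the accompanying tests do — and do
not — establish.

## The sequential synthesis model

Variables are synthesised one at a time along a *visit sequence*
$x_{(1)}, x_{(2)}, \dots, x_{(p)}$. The first variable is drawn by marginal
resampling: each synthetic value is an independent uniform draw (with
replacement) from the observed column, missing markers included. Every later
variable $x_{(j)}$ is drawn from a model of the observed
$x_{(j)} \mid x_{(1)}, \dots, x_{(j-1)}$, evaluated at the
*already-synthesised* predictor rows. The joint synthetic distribution is
therefore the product of fitted conditionals
$\hat f(x_{(1)})\prod_{j>1}\hat f(x_{(j)} \mid x_{(<j)})$ — the same
factorisation used by chained-equations imputation, except that every cell is
replaced, not only the missing ones.

The default column model is a classification or regression tree (CART,
fitted with `rpart`). Donor sampling makes the tree a conditional
*distribution* rather than a point predictor: each synthetic row is routed
down the fitted tree to a leaf, and the returned value is drawn uniformly
from the observed target values in that leaf. Categorical draws use the
leaf's class proportions, which is the same thing. Values outside any
trained split range are routed by the tree's default/surrogate branch, never
an error. Parametric alternatives are available per column: `norm` (linear
model plus Gaussian residual noise), `logit` and `polytomous` (draws from
predicted class probabilities); a singular or inestimable fit falls back to
marginal donor sampling with a warning.

Two consequences of donor sampling matter for users. First, *support
containment*: without smoothing, every synthetic value is an observed value
of its column — realistic supports (integer scores, detection limits) are
preserved automatically, but exact-value disclosure is possible, which is
why disclosure control below is mandatory, and why a smoothing option
exists. Second, the conditional distributions are empirical, so very small
leaves reproduce fine structure at the cost of a higher replicated-unique
rate — the utility/disclosure trade-off is controlled by the leaf size.

### Ordering, predictors, tuning parameters

* **Visit sequence** — defaults to column order. Order can matter; placing
  the analysis exposure and outcome *last* often preserves their relations
  best, so `synthesis_plan(outcome_last = ...)` and the CLI's
  `--outcome-last` expose that heuristic without hard-coding it.
* **Predictor matrix** — defaults to "every strictly earlier variable
  predicts each target". Validation rejects any matrix that is not
  lower-triangular under the visit order, so the engine can never request a
  predictor that has not been synthesised (an execution trace recorded in
  the release provenance asserts this at run time).
* **CART controls** — minimum leaf size 5 and complexity threshold
  `cp = 1e-8` (units: proportional reduction in fit). Small leaves are
  needed for faithful conditionals; both are plan-configurable, and raising
  the leaf size is the first lever when replicated uniques are too many.
* **Smoothing bandwidth** — Gaussian kernel jitter for listed continuous
  columns; the bandwidth follows the normal-reference rule
  (`stats::bw.nrd0`) on the synthetic column because no bandwidth is
  canonical for this purpose. Smoothed values are clipped to the observed
  range.
* **Seeding** — each column consumes a private RNG stream derived from
  `(plan seed, column position)`, so identical inputs are bit-reproducible
  and editing downstream plan entries leaves upstream columns unchanged.

### Missing data

The synthesis must preserve relations between missingness and other
variables, not just between values. Categorical columns carry `NA` as an
explicit level of the column model, so the missingness pattern is learned
jointly with the values. Continuous columns are synthesised in two stages: a
binary missingness indicator by the column's method, then values modelled on
the observed non-missing rows only — this keeps linear models well defined
while reproducing the "NA bars" in marginal comparisons. When a continuous
column with missing values acts as a *predictor*, the design contains its
mean-filled values plus a missingness-indicator factor, for both fitting and
routing, so train and predict designs always align.

### Rules

Deterministic rules (`if never smoked, then amount smoked per day is 0`) are
predicates over earlier-synthesised variables that force a target value. A
predicate that evaluates to `NA` does not fire — missing matches no level.
Rules are applied after all columns are drawn; smoothing runs afterwards and
the rules are then re-asserted, because a forced exact zero that got
jittered would defeat the rule's purpose. Rules may chain (one rule's target
feeding a later rule's predicate); validation permits but flags this, since
chained rules are harder to audit.

## Disclosure control

A synthetic row that exactly reproduces an observed record which is *unique*
in the observed data is treated as a disclosure risk (a "replicated
unique"), regardless of how likely an attacker is to recognise it.
`find_replicated_uniques()` flags such rows by exact comparison of the full
value combination — category labels normalised, continuous values compared
bitwise, missing markers included — and reports the share as a percentage of
the observed sample size. `apply_sdc()` removes them, optionally
top/bottom-codes continuous columns at stated quantiles (type-1, so the
bound is an observed value), and re-checks until the release contains zero
replicated uniques; this re-check is the release gate and is asserted on
every pipeline run. `manual_check_sample()` mirrors the traditional by-hand
sanity check: draw rows unique within the observed table and count exact
matches among rows unique within the synthetic table — zero after SDC.

The flagging rule and the manual check intentionally differ: flagging uses
"observed-unique row appears in synthetic" (the stronger condition under
which removal is warranted), while the manual check requires uniqueness
within each table separately, matching how the check is performed in
practice. When smoothing is on, flagging runs on the smoothed (released)
values, because risk must be assessed on what is actually released.

## Utility validation

Two complementary comparisons quantify whether synthesis preserved the
data's structure:

* `compare_marginals()` tallies every variable on shared category
  definitions computed from the observed table — observed level sets with
  `NA` as its own category, continuous variables cut at observed quartiles
  (extended to cover any synthetic value). A synthetic-only category is
  reported with observed count 0: that is a synthesis bug signal, not a
  cosmetic detail. Comparison runs on the post-SDC (released) table by
  default, since that is what users will see; pre-SDC comparison is
  available by passing the pre-SDC release.
* `fit_glm_both()` refits one identical model specification to the complete
  cases of each table and reports estimates, standard errors, z-values
  (estimate/SE, a shared scale across coefficients), Wald 95% intervals and
  their overlap. The overlap measure is the symmetrised interval-overlap
  fraction — shared length divided by each interval's width, averaged —
  which is 1 for identical intervals and 0 for disjoint ones; the field uses
  several variants and none is canonical, so we chose the symmetric one and
  state it here.

## Longitudinal validation

Repeated measures are synthesised strictly in **wide** format (one row per
individual): long-format synthesis would treat rows of the same person as
independent and destroy within-person correlation, so the pipeline refuses
it. Fidelity is then quantified on the long representation with a multilevel
quadratic growth model: fixed intercept, age and age² (age centred at 12
years by default), optionally a female main effect and both interactions,
with correlated random intercept and age/age² slopes per individual and an
unstructured covariance. Estimation is maximum likelihood, not REML, so fits
on observed and synthetic tables of different sizes remain comparable;
fixed effects carry Wald intervals. Random-effect (co)variances are reported
as point estimates without standard errors — Wald SEs for variance
components are unreliable near the boundary, which is why `lme4` does not
produce them; comparisons of random effects are therefore on estimates only.
Non-convergence triggers one retry from a different optimiser before the
failure is reported.

## The fixture generator

Because the motivating cohort data are restricted, the package ships a
generator whose *structure* mimics two canonical shapes — with every
generating parameter chosen here and recorded in a truth record, never
copied from any cohort's estimates:

* a 15-variable cross-sectional table (child sex, birthweight ~ N(3.4,
  0.45²) kg conditional on gestation ~ N(39.4, 1.9²) weeks, maternal age ~
  N(28, 5²) years, education, social class, housing, marital status,
  ethnicity, parity, pregnancy size; a 0–30 integer depression-score
  exposure drawn binomial-logit so its support is realistic for donor
  sampling; a binary outcome from a logistic model with exposure log-odds
  0.08 per point giving ≈10–15% prevalence; missingness missing-at-random
  through logit models on observed covariates at ≈5–15% per column);
* a wide height panel (8 occasions at target ages 7–18 ± 0.25 years,
  growth truth 150 cm at age 12, 5.5 cm/year linear and −0.25 cm/year²
  quadratic, female offsets 0.5/−1.0/−0.2, random-effect covariance with
  intercept SD ≈ 6.3 cm, residual SD 2.5 cm, 10% occasion-wise
  missingness).

The generator reproduces the *kinds* of structure that matter for testing —
mixed types, bounded integer supports, informative missingness, correlated
confounders, individual growth heterogeneity. It does not reproduce real
data's messiness: measurement error spikes, coding artefacts, monotone
attrition, or heavy-tailed outcomes. Green tests therefore demonstrate that
the machinery is correct and well calibrated under these conditions, not
that any particular real dataset will synthesise well; the audit and
comparison tools exist precisely because that judgement is dataset-specific.

## Numerical and design notes

* Row equality for disclosure checks renders continuous values at 17
  significant digits, so comparison is exact at double precision.
* Split-selection ties in `rpart` resolve to the first-encountered best
  split, making synthesis deterministic under a fixed seed.
* Degenerate inputs: constant columns skip smoothing with a warning;
  single-level categorical targets fall back to marginal resampling; an SDC
  pass that would empty the table aborts with a diagnostic rather than
  releasing nothing.
* Stata export writes version-14 `.dta` with value labels; all Stata missing
  codes (including extended codes) collapse to the single `NA` marker on
  import, because the comparison tools treat missingness as one category.
* The release audit covers the pre-release checklist we implement: variable
  minimisation (< 50 variables, and a note when columns exceed the analysis
  model), zero replicated uniques plus the manual check, generated marginal
  and model comparisons, the constant `FALSE_DATA` first column, the
  disclaimer text, and recorded provenance (seed and plan digest). Auditing
  never mutates release files.

## Problem sizes used in the test suite

The shipped tests exercise the cross-sectional pipeline at 150–5,000 rows
and the panel pipeline at 30–2,000 individuals, with 20-replicate loops for
the parameter-recovery and end-to-end fidelity properties; these sizes give
the asserted 3–4 standard-error tolerances adequate power while keeping a
full run near ten seconds for the unit suite and a few minutes for the
end-to-end properties.

## Known limitations

Sequential synthesis compounds column-by-column approximation error: for a
*fixed* observed dataset the synthetic marginal of a late-visited variable
carries a small dataset-specific drift (well under one percentage point in
our fixtures) on top of binomial noise, which is one reason comparisons of
refit models — not only marginals — belong in every release check. Linked
multi-table synthesis, formal utility statistics (pMSE and relatives),
k-anonymity-style attribute-risk accounting, random-forest and copula
column models, and multiple synthetic replicates per call are out of scope.
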