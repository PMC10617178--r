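---
title: "Methods: covariate-adjusted differential metabolomics with a permutation Storey FDR"
author: "metabperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: covariate-adjusted differential metabolomics with a permutation Storey FDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`metabperm` analyses two-group contrasts of untargeted plasma metabolomics
profiles of the kind produced by global LC-MS/MS platforms: a samples x
metabolites matrix of peak intensities with left-censored missingness
(values below the limit of detection), a biochemical annotation
(metabolite → subclass → major class), and a per-sample covariate table
with a binary exposure (the group contrast) and a mix of continuous,
binary, categorical and ordinal confounders. The package covers the whole
analysis chain — preprocessing, per-metabolite regression, a
covariance-preserving permutation FDR, subclass composites, pathway
over-representation and a random-forest classifier — plus a synthetic
cohort generator that makes every stage testable against known ground
truth.

# Preprocessing

Three steps, in a fixed order:

1. **Minimum imputation.** Each below-LOD cell of metabolite $j$ is
   replaced by the minimum observed value of $j$. Undetectable values are
   low by nature, so the observed minimum is a conservative stand-in.
2. **Median scaling.** Each metabolite is divided by its median, computed
   over all $n$ post-imputation values, so the scaled median is exactly 1.
   The median is taken *after* imputation because imputation comes first in
   the processing order; a median over observed values only is a plausible
   alternative reading, and with up to 80% missingness the two can differ —
   the choice is therefore fixed and documented rather than configurable.
3. **Natural log.** Fold differences are recovered by exponentiation, so
   the base cancels out of every reported quantity, and t-statistics are
   base-invariant.

Metabolites with at least 80% missing values are excluded *before*
imputation (retention requires missing fraction strictly below 0.8).
All three steps are monotone (ranks within a metabolite are preserved) and
median scaling absorbs any positive per-metabolite rescaling, making the
downstream statistics invariant to measurement units. That invariance is
exact in real arithmetic; in floating point it is bit-exact for
power-of-two factors and accurate to rounding error otherwise.

# Per-metabolite model

For each metabolite, the log abundance is regressed by OLS on an intercept,
the 0/1 exposure and the chosen covariates:

$$\log y_{ij} = \alpha_j + \beta_j\,x_i + \gamma_j^\top z_i + \varepsilon_{ij}.$$

Classical homoskedastic standard errors are used — the design intentionally
stays with plain linear regression, the field's default for this analysis.
Categorical covariates are treatment-coded against explicit reference
levels (never-smoker, never-drinker, non-vegetarian, high school,
Calibration substudy by default); psychosocial stress enters as a single
ordinal numeric column. Reference levels only re-parameterise nuisance
terms: the exposure t is invariant to them (tested). Exactly collinear
columns (e.g. a study indicator nested within substudy) are dropped with a
warning by default, or raised as an error with `drop_aliased = FALSE`.
Rows with missing covariates are dropped per model (complete case), with a
logged count.

The **adjusted geometric means** of the two groups are the back-transformed
predicted log abundances at exposure 1 and 0 with every other design column
held at its whole-sample mean. Evaluating both predictions at the same
covariate values makes the ratio of adjusted geometric means equal
$e^{\beta_j}$ exactly — the reported **fold difference** — with a Wald
interval $e^{\beta_j \pm t_{df,0.975}\,\mathrm{se}_j}$. The unadjusted
geometric-mean ratio (`fd_unadjusted`) is emitted alongside, because
published tables sometimes define the fold difference on raw rather than
adjusted values; the adjusted one is primary.

# The permutation Storey FDR

Parametric p-values are fragile here: metabolites are strongly correlated
within biochemical subclasses, and imputation leaves point masses in the
data. The package instead builds an empirical null of the exposure
t-scores that preserves the metabolite-metabolite covariance:

1. Residualize the exposure and every metabolite against the
   covariate-only design $Z$ (intercept included).
2. For each of $B$ draws, apply **one shared permutation** of sample
   indices to the residualized exposure, **re-residualize the permuted
   vector against $Z$**, and compute, for every metabolite, the
   Frisch–Waugh t-score $t = r\sqrt{df/(1-r^2)}$ from the correlation $r$
   with the (unpermuted) residualized metabolite, $df = n - \mathrm{rank}(X)$.

Sharing the permutation across metabolites within a draw is what preserves
the covariances between residualized abundances — the joint distribution
of each null row mirrors the joint distribution of the observed t-scores
under the null, which is what makes $\hat\pi_0$ and the q-values honest
under correlation.

The re-residualization in step 2 (a Freedman–Lane-style refit) matters
quantitatively: a permuted residual vector is no longer orthogonal to the
covariate space, so without the refit the null correlations have variance
about $1/(n-1)$ while the observed statistic has variance $1/(n-p)$. At
$n = 350$ and $p \approx 10$ that is a null about 1.3% too narrow — which
sounds negligible but inflates far-tail exceedance probabilities, and the
realized false-discovery proportion, by 10–20%. With the refit the
unpermuted statistic still reproduces the OLS exposure t exactly (the
observed residualized exposure is already orthogonal to $Z$, so the refit
is the identity on it).

**pi0.** With $c$ the median of the pooled null $|t|$ values,
$\hat\pi_0 = \min\!\big(1, \tfrac{\#\{j: |t_j| \le c\}/m}{\hat P_{null}(|T|\le c)}\big)$,
floored at $1/m$. Small $|t|$ values are dominated by nulls, so the ratio
estimates the null proportion. The single-quantile form is deliberately
simpler than a $\lambda$-grid with spline smoothing; at cohort scale its
variance is acceptable (SD ≈ 0.05 at $m \approx 900$ with within-subclass
correlation 0.5) and it is unbiased to within ~1% in the mixtures the test
suite measures.

**q-values.** For a threshold $c$ equal to an observed $|t_j|$,
$$\widehat{FDR}(c) = \hat\pi_0\, m\, \hat P_{null}(|T| \ge c) \,/\, \#\{k: |t_k| \ge c\},$$
with the pooled-null exceedance probability computed with an add-one rule
$(\#\mathrm{exceed}+1)/(Bm+1)$ so it is never zero (the smallest
attainable q is therefore about $\hat\pi_0/(B+1)$ for a single tested
outcome). The q-value of metabolite $j$ is the minimum $\widehat{FDR}$
over all thresholds that would select $j$, making q monotone
non-increasing in $|t|$, with ties sharing a value. Tests are two-sided
throughout; $B$ defaults to 1000 and is configurable ($B = 200$ already
gives stable selection at $m \sim 800$ because the null pool is $B\,m$
values).

Measured behaviour (see the test suite, which recomputes all of this):
on mixtures with 10% non-null metabolites at 0.5 residual-SD effects,
block correlation 0.5 and confounded covariates at $n = 350$, the realized
false-discovery proportion at $q < 0.05$ averages ≈ 0.05, and the
selection is at least as large as Benjamini–Hochberg applied to the same
permutation p-values (the motivation for the Storey-type estimate: using
$\hat\pi_0 < 1$ and the empirical null recovers power that BH leaves on
the table). Under the global null, $\hat\pi_0$ concentrates near 1 and the
procedure returns zero discoveries on ~95–97% of datasets — an FDR
procedure at $\alpha = 0.05$ necessarily makes at least one null rejection
on a few percent of datasets.

# Subclass composites

The subclass score of a sample is the arithmetic mean of the log values of
the component metabolites — the log of the geometric mean of their scaled
intensities. Regressing this average on the same design yields the
composite t: because the outcome is an average, its regression standard
error mechanically reflects the covariances between components ("dividing
by the standard deviation of the average"). Perfectly correlated
components reproduce the single-component t; independent components with a
shared effect gain power (both asserted in tests). The composite fold
difference equals $\exp(\text{mean of component }\beta_j)$ exactly, since
OLS is linear in the outcome. Subclass q-values reuse the same
shared-permutation machinery on the subclass-average matrix; component
significance counts (total, significant, fold > 1, fold < 1) come from the
metabolite-level table at the same FDR threshold (0.05 by default).

# Pathway over-representation

Significant metabolites are tested against a pathway library (GMT sets)
with the exact hypergeometric upper tail
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, where the universe $N$
is the set of platform-measurable compounds mappable to the library —
compounds outside it are dropped from both pathways and hits, with a log.
P-values are BH-adjusted across pathways (pathway tests are few and
discrete, so the permutation machinery is not reused here). When a pathway
graph is supplied (two-column edge list), the topology impact of the hits
is the sum of their relative betweenness — each node's betweenness divided
by the pathway total — so a pathway's maximum importance is 1 and
zero-betweenness leaves (terminal compounds) contribute nothing. The
library ships nothing: pathway sets and graphs are user-supplied inputs,
never downloaded.

# Random-forest discrimination

Two evaluation schemes, mirroring the two ways a per-tree 70/30 design can
be read:

- **Per-tree holdout** (`train_eval_holdout`): every tree trains on a
  stratified 70% subsample (without replacement by default; bootstrap by
  flag) and predicts its own held-out 30%; overall accuracy is the mean
  per-tree holdout accuracy. Mean decrease accuracy of metabolite $j$ is
  the mean over trees of (holdout accuracy − holdout accuracy with $j$
  permuted). The trees are grown by `randomForest`; the holdout evaluation
  and the permutation-importance loops are computed in this package from
  the per-tree predictions and in-bag records, because standard
  out-of-bag importance is not the same quantity.
- **Stratified 5-fold CV** (`train_eval_cv`): a forest per training fold,
  accuracy averaged over held-out folds, importance as the Gini impurity
  decrease averaged over fold models.

Stratification by class protects near-balanced designs (the package's
motivating cohorts are ~171/179). Defaults are 1000 trees
(50,000 — the full-scale setting — is a config value away) and
`mtry = floor(sqrt(m))`.

One property worth knowing: *mean per-tree* holdout accuracy is not
ensemble accuracy. Individual fully-grown trees overfit, so under null
labels the mean per-tree accuracy sits near 0.5 rather than at the
majority-class rate, and with `mtry` ≪ m even a perfectly separating
metabolite cannot push the mean per-tree accuracy to 1, because trees
whose split candidates never include the separator predict near chance.
The test suite's separability checks therefore set `mtry = m` (bagged
trees); with the default `mtry` the same signal is recovered in the
importance ranking, just with lower mean per-tree accuracy.

# The synthetic cohort generator

The generator emulates the statistical structure this analysis assumes,
with defaults matching the motivating study design: two groups of 171/179
samples, 892 lognormal metabolites in 92 subclasses, block-equicorrelated
log-scale noise within subclass (0.5 by default) and independence across
subclasses, a minority (10%) of metabolites carrying a ±0.5 residual-SD
group effect with random sign, six covariates moderately associated with
group (age, sex, BMI, coffee, social vulnerability, smoking) that also
act on the log abundances (true confounders), an additive per-batch log
shift, and deterministic left-censoring of each metabolite's lowest 20%
("below the limit of detection" is a property of low values, not missing
at random). Everything is reproducible bit-for-bit from the seed, and the
ground truth (non-null set, signed effects, subclass map) is returned.

Choices the data do not dictate, made once: lognormality (the motivating
platform reports no distributional claim; lognormal is the field's
standard working assumption for peak intensities), equicorrelated blocks
(the simplest controllable covariance that exercises the
covariance-preserving null), covariate effects on a random half of
metabolites with N(0, 0.15) log-scale coefficients, batch shifts
N(0, 0.2), baseline log intensities N(10, 1). What the generator does
*not* emulate: heavy-tailed platform noise, metabolite-specific missing
mechanisms, cross-subclass correlation, drift within batch. Passing tests
therefore demonstrate calibration and correctness under the assumed
structure, not robustness to everything real data can do.

# Numerical choices and degenerate inputs

- All per-metabolite fits share one QR decomposition of the design;
  identical results to metabolite-by-metabolite `lm` fits at machine
  precision.
- Constant outcomes are degenerate fits reported with t = 0 and a flag,
  not errors.
- Null correlations with $|r|$ numerically 1 are clamped to t = ±1e6 with
  the sign kept; a zero residualized exposure yields all-zero null t.
- A rank-deficient covariate design is always an error in the permutation
  machinery; in design building it is an error or a logged drop depending
  on `drop_aliased`.
- Ties in $|t|$ share a q-value by construction of the threshold set.
- The degrees of freedom used in the null, $n - \mathrm{rank}(X)$, match
  the permutation geometry exactly after the Freedman–Lane refit (both
  vectors live in the orthogonal complement of the covariate space).

# Problem sizes used by the test suite

The statistical guarantees are exercised at the scale the package targets:
FDR control and the Storey-vs-BH comparison on 25 replicate cohorts of
n = 350 with m = 800 (80 blocks, correlation 0.5, B = 200); global-null
calibration on 100 cohorts at the full platform scale m = 892 / 92
subclasses; parameter recovery on 600 non-null metabolites across three
cohorts; oracle equivalences (Frisch–Waugh, exhaustive hypergeometric
enumeration up to N = 20, naive all-pairs betweenness on graphs of ≤ 8
nodes) at exact tolerances; classifier sanity at 500 trees.

# Known limitations

- Classical OLS standard errors; no robust or mixed-model variants.
- The permutation null assumes exchangeability of residualized samples;
  strong heteroskedasticity by group is not modelled.
- $\hat\pi_0$ uses a single pooled-null quantile; under extreme
  correlation its variance grows and the q-values inherit it.
- ORA treats compounds as exchangeable draws; no abundance weighting, no
  compound-ID translation.
- The per-tree holdout scheme reports mean per-tree accuracy by design;
  it is not comparable to ensemble-vote accuracy.
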