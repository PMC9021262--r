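---
title: "Growth shocks and child wasting: methods notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth shocks and child wasting: methods notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the modelling choices behind `wastingshocks`: the
estimating equation and its assumptions, what the synthetic-data generator
does and does not emulate, the numerical conventions, and the places where
the design was genuinely open and a choice had to be made.

## The estimating equation

The package fits weighted linear probability models of a binary wasting
indicator on a shock-by-prevalence interaction:

$$
w_{i,c,r,t} = \beta_0 + \beta_g\,\bar{w}_c\,\frac{g_{c,t-1}}{10}
  + \boldsymbol{\beta}_X' \mathbf{X}_{i}
  + \text{country FE} + \text{region}\times\text{age}
  + \text{region}\times\text{month} + \text{region}\times\text{5-yr}
  + \varepsilon_{i,c,r,t}
$$

* `g` is **simple percent change** of per-capita income levels, not a log
  difference. The burden calculator's published arithmetic only closes
  under simple percent changes, and the two are nearly identical at the
  growth rates involved.
* `g` is divided by 10 so that the coefficient reads "per 10% change in
  income growth".
* The long-run mean prevalence enters **as a proportion** (0–1). With a 0/1
  outcome this makes the coefficient an exact elasticity:
  \( \Delta \text{prev} = \beta_g\,\bar{w}_c\,g/10 \), hence
  \( \Delta \text{prev}/\bar{w}_c = \beta_g\,g/10 \).
* `wbar_c` is computed as the survey-weighted prevalence **per round**,
  then averaged unweighted across the country's rounds, so a huge recent
  round does not dominate the country mean.
* Lag convention: a child interviewed in year *t* is matched to growth in
  year *t − 1*, i.e. the level change from *t − 2* to *t − 1*. The lag
  guarantees that the shock precedes the anthropometry and accommodates
  delayed transmission of income losses into child weight. Mechanism
  regressions (below) use contemporaneous growth (lag 0).
* Because country fixed effects absorb \( \bar{w}_c \cdot \overline{g}_c \),
  the identified coefficient measures the response to *deviations from the
  country's long-run growth trend*. The test suite verifies the implied
  invariance: adding a constant to one country's entire growth path leaves
  \(\hat\beta_g\) unchanged.

The key identifying assumption, as in any fixed-effects design of this
type, is that within-country deviations of lagged growth from trend are
uncorrelated with unobserved child-level wasting determinants conditional
on the temporal controls. The package makes no attempt to relax this
(options exist for extra country-year controls — e.g. lagged rainfall,
temperature, battle deaths — and for trimming extreme growth rates, as
robustness devices).

## Survey weighting

Pooling surveys across countries with arbitrary sample sizes would
implicitly weight growth episodes by survey size. The composite weight is
the product of three factors:

1. **country factor** \((\text{pop}_c/\sum \text{pop}) / (n_c/\sum n)\) —
   weight shares equal under-5 population shares;
2. **round factor** \(\overline{n}_{\text{rounds in } c} / n_r\) — every
   round of a country carries equal total weight;
3. the **design weight** as supplied (taken as already normalized within
   its survey, the usual convention).

The composite is rescaled to sum to the number of child records. The data
do not pin this constant down and weighted-least-squares estimates are
invariant to it (tested); summing to N merely keeps nominal sample sizes
readable.

## Inference

Standard errors are clustered at the country level: the shock varies only
at country-year, and within-country dependence is the dominant concern.
Two clustered-variance flavours are provided.

* **CR1** — the sandwich over cluster score sums with the
  \( G/(G-1) \cdot (N-1)/(N-k) \) factor and t critical values with
  \(G-1\) degrees of freedom: the dominant convention of the applied
  software this design descends from, and the convention behind published
  tables of this kind. It is verified against an independently coded
  brute-force sum-of-outer-products sandwich to 1e−10.
* **CR3** (default) — the cluster jackknife: refit leaving out one cluster
  at a time (computed by downdating the normal equations, with per-subset
  pruning of columns the omitted cluster supported) and take
  \((G-1)/G \sum_g (\hat\beta_{(-g)} - \bar\beta)(\cdot)'\). Verified
  against a brute-force leave-one-cluster-out refit.

CR3 is the default because simulation exposed a serious failure of CR1 in
exactly this design: when country fixed effects and region×time dummies
absorb most of the country-year variation of the shock, the residual-based
cluster score sums are strongly shrunk and CR1 *halves* the true sampling
standard error. This was verified against the exact conditional variance
(computable in the generator, where each child's Bernoulli probability is
known): on a representative 40-country design the true SE of the elasticity
was 0.054 while CR1 reported 0.027, giving ~60–78% coverage for a nominal
95% interval. The jackknife restores approximately nominal coverage. The
downward bias of CR1 with few effective clusters and high-leverage
cluster-level regressors is well documented in the cluster-robust inference
literature; this package simply defaults to the estimator that is
calibrated in its own testable world, and keeps CR1 one flag away
(`small_sample = "CR1"`) for convention-matching output.

Published-style tables use two-sided 95% CIs; a 90% level can be requested
where one-sided displays are wanted (`conf_level = 0.90`).

With many fixed-effect blocks the design is rank deficient by
construction (country dummies nested in region blocks, sparse region-age
cells). Collinear columns are detected by pivoted Cholesky on the
correlation-scaled normal matrix and dropped *by name* rather than silently
generalized-inverted. The shock column is special-cased: all other columns
are pruned first, and if the shock then lies in the span of the retained
basis (Schur complement ≈ 0) estimation aborts — the elasticity is not
identified. This situation is real, not hypothetical: with one country per
region, region×5-year dummies reproduce the country-year shock exactly.

A practical finding from the simulation studies: the region×bracket
dummies absorb much of the country-year shock variation, so single-dataset
estimates are noisy at small country counts even when the estimator is
exactly unbiased (the generator's conditional mean is linear in the
regressors by construction). Recovery checks therefore compare replicate
means against Monte-Carlo standard errors rather than single draws.

## Mechanism and subgroup variants

Mechanism regressions replace the outcome with diarrhea, fever-only, low
maternal BMI, or minimum dietary diversity (MDD), interact
*contemporaneous* growth with the mechanism outcome's own country mean, and
(for MDD) restrict the sample to children 6–35 months, the indicator's
defined age range. "Fever-only" is treated as an opaque binary column; the
package imposes no definition of its own.

Subgroup variants add `shock × urban` and/or `shock × girl` columns; a
constant subgroup indicator in the sample drops the interaction with a
warning instead of producing a zero-variance column.

## The synthetic-data generator

Real DHS-style microdata are access-restricted, so the generator produces
a world in which the estimating equation is *exactly correctly specified*
and the elasticity is known:

* macro series: GDP per-capita levels follow
  \( Y_t = Y_{t-1}(1 + \mu_c + \varepsilon_{c,t}) \) with country trends
  \(\mu_c \sim N(0.02, 0.01)\) and annual deviations
  \(\varepsilon \sim N(0, 0.05)\) — typical LMIC magnitudes. GNI growth
  adds independent noise with variance \(\sigma^2(1/\rho^2 - 1)\),
  calibrating the pooled GNI–GDP growth correlation to 0.90, the value
  observed in the real multi-country sample this design emulates.
* wasting probability:
  \( p = \text{clamp}\big(\bar{p}_{c,k}(1 + \beta\,g_{t-1}/10)
  + r_k(\delta_{\text{age}} + \delta_{\text{month}} +
  \delta_{\text{region-trend}} + \gamma' X)\big) \)
  for indicator *k*. Every additive term is a function of one regressor
  block, so the estimator applied with the true \(\bar p_c\) is unbiased by
  construction — that is the point of the generator.
* the structural shift is scaled per indicator by the baseline ratio
  \( r_k \) (severe 0.4×, any 2.2× the moderate/severe shift): rarer
  outcomes move less in absolute probability. Without this scaling,
  plausible covariate effects push severe-wasting probabilities (baselines
  1–10%) below the floor; the generator's own clamping guard rejected the
  unscaled world, and the scaling is the structural fix.
* the three indicators are thresholded on a **single latent uniform**, so
  severe ⊆ moderate/severe ⊆ any holds exactly while each indicator keeps
  its marginal probability. Probabilities are clamped to [0.001, 0.999]
  (configurable); if more than 1% of child-indicator probabilities need
  clamping the configuration is rejected as internally inconsistent rather
  than silently distorted. A final `pmax` enforces the probability ordering
  in corner cases where the per-indicator scaling could invert it; it binds
  with negligible probability.
* survey structure: 2–4 rounds per country at random years; round sizes are
  the base size times a log-uniform multiplier on [0.25, 4] — deliberately
  unequal, to exercise the round-balancing weights (the within-country
  distribution of real round sizes is not documented; log-uniform is a
  stand-in). Design weights are i.i.d. gamma with mean 1.
* covariates: three-level asset class with shares 34% none / 7% all five
  (observed shares in the emulated sample), plus the standard
  household/maternal binaries at plausible LMIC frequencies.
* mechanisms: each mechanism outcome gets its own country baseline and a
  planted *contemporaneous*-growth elasticity (defaults: diarrhea −0.12,
  fever-only −0.18, low maternal BMI −0.14, MDD +0.19 — signs and rough
  magnitudes of the published mechanism estimates); MDD is missing outside
  6–35 months.
* one global seed fans out to fixed per-stream sub-seeds (macro, children,
  mechanisms), so adding a stream never perturbs another, and identical
  seeds give byte-identical CSV output.

What the generator does **not** emulate: DHS cluster/stratum sampling
geometry (design weights are i.i.d., so design-based variance features are
absent), measurement error in WHZ, within-household correlation, migration
between regions, or any non-linearity in the shock response. A green
recovery test therefore establishes that the estimator is correct *under
its own assumptions*, not that those assumptions hold in real survey data.

## The burden calculator

For a projection year, `shock = g_year − mean(g over the reference
decade)` (simple mean; the published single-country example closes under
this choice within printed rounding), and
`prev_out = prev_in (1 + elasticity · shock/10)`, clamped to [0, 100] with
a logged message. Default elasticity −0.178 (the GDP moderate/severe
estimate); the GNI companion value −0.144 can be passed instead. Counts are
carried at full float precision and rounded to whole children only at
display. Regional aggregate rows are sums over country rows — they are
*not* recomputable from the rounded regional shock/prevalence averages,
which is why a published regional row's own arithmetic does not close while
a single-country row's does.

## Numerical conventions and degenerate inputs

* WHZ plausibility filter |WHZ| ≤ 5 (the conventional flagging band) before
  classification; excluded records are counted and reported. Whether the
  emulated analyses applied such exclusions is undocumented; the filter is
  configurable.
* Prevalence bands are half-open: [0,5), [5,10), [10,15), [15,100].
* 5-year brackets are anchored at 1990 (1990–94, 1995–99, …); anchoring is
  otherwise arbitrary and absorbed by the dummies.
* Reference categories: lexicographically first level per dummy block,
  "none" for asset class; recorded in the fit object.
* Missing data: listwise deletion with a per-column missingness report;
  children whose lagged growth is unavailable are excluded and counted.
* An outcome that is identically zero yields all-zero coefficients and a
  reported R² of 0 (the weighted total sum of squares is 0; the 0/0 is
  resolved to "no variance explained").
* The growth correlation target must be positive: the calibration adds
  independent noise and cannot produce ρ ≤ 0; such configurations are
  rejected with an explanatory message rather than silently ignored.
* Age profiles use a triangular-kernel moving average (default bandwidth 3
  months; bandwidth 0 degenerates to raw per-age prevalences) — a
  simplified stand-in for local-polynomial fits, without confidence bands.

## Monte-Carlo test sizes

The acceptance suite keeps the stated study design exactly (40 countries ×
3 rounds × 2,000 base children, planted elasticity −0.15) and reduces only
replicate counts to fit a one-CPU budget: 40 replicates for recovery
(the 2-Monte-Carlo-SE bound scales with the actual replicate count, so
fewer replicates make the check *wider in absolute terms but no weaker as
evidence*) and 100 replicates for CI coverage against the 95% ± 4 pp band.

## Known limitations

* No logit/probit alternatives; linear probability only.
* No replicate-weight or jackknife variance machinery for the survey
  design.
* The region-subset question (whether country population factors should be
  re-normalized within a region when fitting regional subsets) is resolved
  by always applying the global factors.
* Real-data coefficient tables cannot be reproduced here: the microdata
  are restricted. The package's evidence is the synthetic recovery and the
  desk-checkable projection arithmetic.
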