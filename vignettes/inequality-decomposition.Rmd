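---
title: "Measuring and decomposing empowerment-related inequality in maternal health care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing empowerment-related inequality in maternal health care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svyconc)
```

## The problem

Maternal health care services — early antenatal care, a sufficient number
of ANC visits, ANC of adequate content, and timely postnatal care — are
often used unequally across social groups. `svyconc` quantifies such
inequality when women are ordered by an *ordinal* equity stratifier, such
as the three SWPER women's-empowerment domains (attitude to violence,
social independence, decision-making), each coded low / medium / high, and
then explains the measured inequality in terms of the covariates that
drive it. All computations respect a complex sampling design: unequal
sampling weights, stratification and clustering, and pooling of several
survey rounds.

## The measures

**Fractional ranks.** Women are ranked by the stratifier using weighted
fractional ranks. Every member of a tied category $c$ with weighted
population share $w_c$ and cumulative share $W_c$ below it receives
$r = W_c + w_c/2$. With only three ordinal levels, within-category
ordering is undefined, so the category-midpoint convention is the natural
tie rule; it guarantees a weighted mean rank of exactly $1/2$.

**Concentration index.** For health variable $h$ with weighted mean
$\bar h$,
$$CI = \frac{2}{\bar h}\,\mathrm{cov}_w(h, r),$$
twice the area between the concentration curve and the line of equality.
$CI > 0$ means $h$ is concentrated among the advantaged (highly ranked).

**Erreygers normalization.** For binary outcomes the standard index's
attainable range depends on prevalence, so the package reports
$$ECI = \frac{4\bar h}{y_{max}-y_{min}}\,CI = 8\,\mathrm{cov}_w(h, r)$$
(range 1 for binary variables). The ECI measures absolute inequality, is
bounded by $\pm 4\bar h(1-\bar h)$ with equality under perfect
concentration, and satisfies the mirror property
$ECI(1-h) = -ECI(h)$, so attainment and shortfall inequality never have to
be computed separately.

**Decomposition.** A survey-weighted binomial-logit model
$\mathrm{logit}\,P(h=1) = \beta_0 + \sum_k \beta_k x_k$ over dummy-coded
covariates yields derivative-form average marginal effects
$ME_k = \beta_k\,\overline{p(1-p)}$ (weighted mean). Each dummy then
contributes
$$100 \times \underbrace{\frac{ME_k\,\bar x_k}{\bar h}}_{\text{elasticity}}
  \times \frac{CI_k}{CI} \quad\text{percent},$$
where $CI_k$ is the dummy's own concentration index against the same
ranking. The residual percentage — the generalized concentration of the
linear-approximation error — is reported explicitly, so contributions plus
residual always total 100%; that additivity is the key testable identity
of the procedure. Because the Erreygers factor $4\bar h$ cancels from the
ratio, the same percent contributions decompose the standard and the
Erreygers index.

### Why derivative marginal effects

Discrete-change marginal effects (flip the dummy for everyone) are a
common software default, but they break the additive identity on which
the decomposition rests. The derivative form is the exact linearization
of the logit surface, which is what the contribution algebra assumes.
The cost is approximation error when effects are strong: in the extreme,
an outcome that is a *deterministic* step function of a covariate drives
$\beta_k \to \infty$ while $\overline{p(1-p)} \to 0$ and the linearization
degenerates (the residual absorbs everything). In the weak-to-moderate
effect regimes typical of survey logit models the residual stays small; a
validation test confirms a sole-driver stratifier with moderate effects
receives ~100% attribution.

## Design-based uncertainty

The default standard error uses the *convenient regression* identity: the
weighted least-squares slope of $h$ on $r$ equals
$\mathrm{cov}_w(h,r)/\sigma_r^2$, so $ECI = 8\sigma_r^2 b$ and
$se(ECI) = 8\sigma_r^2\,se(b)$. The slope variance is Taylor-linearized
for a stratified cluster design: influence values are summed within
primary sampling units, and each stratum with $n_h$ clusters contributes
$\tfrac{n_h}{n_h-1}\sum_c (z_{hc}-\bar z_h)^2$. Intervals use a $t$
reference on (clusters − strata) degrees of freedom, matching standard
survey practice. In a single stratum this estimator coincides exactly with
the usual cluster-robust (sandwich) variance, which the test suite
verifies against an independent implementation.

A stratified cluster bootstrap (resample clusters with replacement within
strata, re-rank, recompute; percentile intervals, default 1000 seeded
replicates) is provided as a cross-check. The two can differ in the third
decimal; both are labelled in the output. Strata containing a single
cluster carry no between-cluster information: under linearization they are
collapsed into a pseudo-stratum with a warning; under the bootstrap they
are a design error, since within-stratum resampling needs at least two
clusters.

Degenerate inputs are rejected rather than silently absorbed: a
single-category stratifier (ranking undefined), zero prevalence (index
undefined), and zero outcome inequality in the decomposition (percent
contributions undefined; the error suggests reporting absolute
contributions $elasticity \times CI_k$ instead).

## Pooling several survey rounds

When rounds are appended, weights are rescaled within each survey so every
survey's weights sum to a common `target_total` (default 1 — any common
constant makes the surveys "count equally", and 1 makes per-survey totals
easy to audit). Stratum and cluster labels are prefixed by the survey
label, because identical labels in different rounds are different design
units. Within a single survey, rescaling is a scale factor and leaves all
ranks and weighted statistics unchanged.

Missing and "don't know" covariate responses are recoded into the
covariate's designated least-advantaged category (e.g. "no occupation"),
never dropped, so denominators are preserved; outcomes with inapplicable
components (no birth in the window) are `NA` and excluded per outcome, so
each outcome keeps its own analysis N.

## Empowerment scoring

Domain scores are linear combinations
$\sum_j \lambda_j (x_j - c_j)/s_j$ over 14 standard DHS items, with
loadings, centering/scaling constants and two cutpoints per domain
consumed from an editable JSON asset; the package never re-estimates the
principal-component loadings, which would require multi-country microdata.
The shipped asset is a clearly labelled *synthetic placeholder*
(`swper_weights_synthetic.json`); users must paste in the published SWPER
Global constants for real analyses. The score-to-category boundary is
left-closed above (a score exactly at a cutpoint promotes), a convention
we fix and test because sources are typically silent about it; scoring is
affine-equivariant, so consistent rescaling of items and constants cannot
move anyone across categories. A domain can be flagged unavailable for the
earliest round (as decision-making is in some survey series) and is then
analyzed on the remaining rounds only.

## What the synthetic generator emulates — and what it does not

`generate_pooled_survey()` mimics a two-stage stratified cluster sample:
strata containing clusters, a fixed number of women per cluster, and
lognormal cluster-level weights centred at 1 (normalized per survey),
standing in for unequal selection probabilities without modelling a real
census frame. One latent socioeconomic factor $z$ with variance split
across stratum / cluster / woman levels (defaults 0.05 / 0.15 / 0.80)
induces realistic intra-cluster correlation while keeping the marginal of
$z$ exactly N(0,1). Each categorical covariate and empowerment domain
derives from its own Gaussian latent correlated with $z$ (a one-factor
copula), so covariates have nonzero concentration indices against the
empowerment ranking — the correlation structure a decomposition needs.
Outcomes follow a logit model with known coefficients.

Because the marginal model is fully specified, the *true* population ECI
is computable: by Monte-Carlo enumeration of a large i.i.d.
superpopulation using expected outcome probabilities (no Bernoulli noise),
or exactly by one-dimensional quadrature over $z$ with the discrete cell
space enumerated. The two routes agree to a few $10^{-4}$ at a
$2\times10^5$ superpopulation, and an outcome held entirely by the top
equal-share tertile reproduces the closed form $ECI = 4p(1-p) = 8/9$ to
$10^{-9}$.

Defaults are one fixed choice of plausible study conditions: four rounds,
22 strata per survey (a region-by-urban/rural layout), 10 clusters per
stratum, 25 women per cluster, weight dispersion 0.3, equal-share
empowerment tertiles, covariate gradients and secular year effects of
moderate logit magnitude, and intercepts placing the four outcome
prevalences between roughly 0.19 and 0.38. Missingness defaults to zero;
injection is explicit and seeded.

The generator does **not** reproduce any real country's marginals,
geography or census frames, household rosters, informative (outcome-
dependent) sampling, or nonresponse mechanisms. Passing validation on
synthetic data therefore demonstrates the *estimators* are correct under a
faithful design structure; it does not certify substantive estimates on
any real survey.

## Validation choices and problem sizes

The validation suite uses: exact finite populations (weighted cells) for
closed-form checks; 100 random fixtures (n up to 500, lognormal weights)
for the three-route oracle equivalence ($8\,\mathrm{cov}$, regression
slope, curve area; agreement within $10^{-6}$) and the sign symmetries;
and 200 simulation replicates of a pooled design with 2 surveys × 20
strata × 10 clusters × 25 women (10,000 women per replicate) against a
$10^6$-unit enumerated truth for estimator recovery (bias within 3
Monte-Carlo SEs) and interval coverage (91–99% acceptance band around the
nominal 95%). The null configuration severs the stratifier from both the
SES factor and the outcome model; mean ECI is then statistically zero and
every covariate's mean absolute percent contribution is compared against
its own permutation null, because percent contributions divide by a
near-zero index under the null and only a distributional comparison is
meaningful there. These sizes were chosen to make Monte-Carlo error small
relative to the tested tolerances while keeping a routine validation run
around a minute.

## Known limitations

* Percent contributions are ratios; they are unstable whenever the
  outcome's concentration index is near zero, and the package refuses to
  compute them at exactly zero.
* The decomposition is a linearization: with very strong effects the
  residual grows, and in the deterministic-outcome limit it absorbs the
  entire index (see above).
* No dominance tests between concentration curves, no Wagstaff or
  extended ($\nu$-parameter) index family, no Oaxaca-type between-group
  or over-time decomposition, and no standard errors on individual
  contributions.
* The linearized and bootstrap intervals may differ slightly; neither is
  privileged, and the output records which was used.

## A compact run

```{r example, eval = FALSE}
cfg <- synth_config(seed = 1)
gen <- generate_pooled_survey(cfg, truth_method = "quadrature")

res <- run_analysis(run_config(
  data = gen$data,
  outcomes = c("quality_anc", "pnc2days"),
  domains = c("attitude_to_violence", "decision_making"),
  covariates = c("residence", "wealth", "education", "age_group", "occupation"),
  domain_filters = list(decision_making = c(2005, 2011, 2016)),
  seed = 1))

res$quality_anc.attitude_to_violence$concentration
interpret_signs(res$quality_anc.attitude_to_violence$decomposition)
subset(gen$truth$table, outcome == "quality_anc")
```
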