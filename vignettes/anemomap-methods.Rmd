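---
title: "Model-based geostatistical mapping of anemia severity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based geostatistical mapping of anemia severity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The estimation problem

Anemia in women of reproductive age (WRA, ages 15–49) is monitored through
household surveys that measure hemoglobin concentration in a sample of
women clustered at surveyed communities. Policy questions — where is the
burden, is it mild or severe, is a country on track for the WHO Global
Nutrition Target (GNT) of halving anemia relative to 2012 — require
estimates on a fine spatial grid and for every administrative unit and
year, far beyond what the survey locations cover directly.

`anemomap` implements the full model-based geostatistics (MBG) workflow
for this problem: hemoglobin adjustment and WHO severity classification,
stacked-ensemble covariate modeling, a continuation-ratio ordinal
binomial model with a space–time Gaussian process, posterior-draw
post-estimation (population-weighted aggregation, affected counts, years
lived with disability), calibration ("raking") to an external national
series, logit-space trend projection, and spatially stratified
cross-validation. Everything is exercised end-to-end on synthetic data
with known ground truth, so every layer of the stack is testable.

# Data preparation

**Hemoglobin adjustment.** Raw hemoglobin (g/dl) is lowered by a
residential-elevation decrement (binned lookup, 0 at sea level, rising to
several g/dl above 4,000 m) and a smoking decrement (default 0.3 g/dl).
Both tables are configuration data (`adjustment_tables()`), not code:
published adjustment conventions differ in detail and the exact values
must be overridable. Records carry a provenance flag (`raw`,
`smoking-adjusted`, `elevation-adjusted`, `fully-adjusted`) and each
adjustment is applied exactly once; fully adjusted inputs pass through.

**Severity classification.** WHO thresholds by pregnancy status, with
bands closed on the left and open on the right: for non-pregnant women
severe < 8.0, moderate [8.0, 11.0), mild [11.0, 12.0), non-anemic ≥ 12.0
g/dl; pregnant bands sit 1 g/dl lower. The closed/open convention makes
the printed band endpoints (e.g. "11.0–11.9") unambiguous.

**Collapsing and polygon resampling.** Classified records are collapsed
to cluster-year binomial totals $(N_d, C_d,$ mild, moderate, severe$)$
after an inclusive 15–49 age filter. Survey records referenced only to an
administrative polygon are resampled to pseudo-points drawn among the
polygon's grid cells with probability proportional to population; the
number of points is one per 10 cells (clamped to [1, 100]), each carrying
the full counts with weight $1/k$ so the weights sum to one and the
weighted effective sample size equals the areal $N$. The weight scales
each pseudo-point's log-likelihood contribution, so one areal record acts
as one effective observation.

# The geostatistical model

Each of three continuation-ratio stages is a binomial logit mixed model.
Stage 1 models overall anemia $C_d \sim \mathrm{Bin}(N_d, p_{i(d),t(d)})$;
stage 2 the probability of mild given anemic (denominator $C_d$); stage 3
severe given moderate-or-severe. For a cell $i$ and year $t$:

$$\mathrm{logit}(p_{i,t}) = \beta_0 + X_{i,t}\beta + Z_{i,t} +
\epsilon_{ctr(i)} + \epsilon_{i,t}, \qquad \textstyle\sum_{h=1}^3 \beta_h = 1$$

where $X_{i,t}$ are the three stacker predictions (logit scale),
$\epsilon_{ctr} \sim N(0, \gamma^2)$ are iid country intercepts,
$\epsilon_{i,t} \sim N(0, \sigma^2)$ is an observation-level nugget, and
$Z$ is a zero-mean Gaussian process with separable covariance
$\omega^2\, \Sigma^{space} \otimes \Sigma^{time}$: a Matérn spatial
kernel with smoothness $\nu = 2$ and scale $\kappa = \sqrt{8\nu}/\delta$
($\delta$ = range in degrees, the distance at which correlation falls to
about 0.1), and an AR1 annual kernel $\rho^{|k - j|}$. The sum-to-one
constraint on the stacker weights is enforced exactly by
reparameterization ($\beta_3 = 1 - \beta_1 - \beta_2$, with the third
stacker as offset), so the linear predictor is an affine combination of
submodel logits plus a free intercept.

**Low-rank field.** The GP is supported on a regular knot lattice
(default $9 \times 9$ over the grid extent) with the Matérn kernel
evaluated directly between knots and bilinear interpolation to
observation and prediction points. This is the package's equivalence
contract: the same model family as a finite-element SPDE approximation,
but desk-scale and fully checkable — the structured Kronecker algebra
(log-determinant, solve, quadratic form, sampling) is tested to 1e-8
against dense-matrix brute force. Distances are Euclidean on degrees; at
the package's domain sizes (a few degrees) great-circle corrections are
negligible.

**Model variants.** A config switch selects
`raw` (raw covariates), `raw_gp`, `stackers`, `stackers_gp` (the
standard model), mirroring the four-way sensitivity analysis. The `*_gp`
variants include $Z$; the stacker variants use the constrained weights.

# Inference

Inference is empirical-Bayes MAP with a Laplace approximation, in the
spirit of INLA/TMB but self-contained:

* Transformed hyperparameters $\theta = (\log\omega^2, \log\delta,
  \mathrm{atanh}\,\rho, \log\gamma^2, \log\sigma^2)$ carry weakly
  informative normal priors. Defaults: $\log\omega^2 \sim N(\log 0.25,
  1.5^2)$, $\log\delta \sim N(\log(0.4\,\mathrm{extent}), 1)$,
  $\mathrm{atanh}\,\rho \sim N(1, 1)$, $\log\gamma^2$ and $\log\sigma^2
  \sim N(\log 0.05, 1.5^2)$; all config-exposed.
* For each $\theta$ the latent state (fixed effects, knot field, country
  effects, nuggets) is maximized by Newton iterations with step halving.
  The nugget block is eliminated analytically (its Hessian block is
  diagonal), so the factored system is only (fixed + knots + countries)
  square — the Schur complement with effective weights
  $\tilde W = W/(1 + \sigma^2 W)$.
* The Laplace log marginal posterior is maximized over $\theta$ by
  Nelder–Mead (Brent in one dimension) and polished by BFGS on a
  deterministic re-evaluation; its curvature is a central-difference
  Hessian (step 0.05 on the transformed scale).
* Posterior draws (default $D = 1000$) are allocated among
  `theta_draws` (default 20) hyperparameter values sampled from the
  Gaussian approximation $N(\hat\theta, \hat\Sigma_\theta)$; for each,
  the latent conditional is re-moded and sampled exactly from its
  Gaussian. This propagates hyperparameter uncertainty into every
  downstream quantity without a full MCMC.
* Stages are fitted independently; their draws are paired by index when
  composing marginals. The pairing is arbitrary but fixed — the stages
  share no parameters, so any pairing yields the same marginal
  distributions.

Marginal severities are composed draw-wise: mild $= p \cdot q_2$, severe
$= p (1 - q_2) q_3$, moderate the residual, so mild + moderate + severe
$= p$ exactly in every draw.

**Numerical safeguards.** The $\nu = 2$ Matérn correlation matrix is
numerically rank-deficient once $\delta$ exceeds the knot spacing, so the
spatial factor carries a 1e-6 diagonal jitter (identical in the
structured and dense-oracle paths). Cholesky factorizations get an
escalating ridge repair on failure. The hyperparameter Hessian's
eigenvalues are floored at 0.1, capping the dispersion of the
$\theta$ draws in directions the data leave unidentified. Boundary
prevalences are nudged by 1e-6 before logits.

# Stacked ensemble

Three child learners per stage — a penalized additive smooth model
(`mgcv::gam`), gradient-boosted trees (`xgboost`, 150 rounds, depth 3,
$\eta = 0.1$, single thread), and lasso-penalized logistic regression
(`glmnet` on covariates plus squares and pairwise products, $\lambda$ by
internal CV) — are standard stand-ins for the named trio (GAM, BRT,
lasso); the learner trio is standard but its tuning is not, so
hyperparameters are fixed config defaults. Per-observation
predictions are strictly out-of-fold (5 folds stratified by cluster);
grid predictions come from an all-data refit. All predictions enter on
the logit scale, so the constrained combination stays an affine
combination of logits. Conditional stages (2 and 3) are fit on the
conditional denominators. A degenerate response (all zero / all success)
makes every learner return the pooled empirical logit, with a warning.

# Post-estimation

Masking precedes aggregation: cells below 10 persons per km² (threshold
scaled by the actual cell area) or labeled barren/sparsely vegetated are
set to missing and contribute neither numerator nor denominator anywhere
downstream. Unit-level prevalence is the population-weighted mean of cell
draws, applied per draw; WRA counts are a configured fraction (default
0.25) of the population raster in the absence of an age–sex structure
raster; YLDs multiply severity counts by disability weights (defaults
0.004/0.052/0.149 mild/moderate/severe — convention, config data).
Public-health-problem classes use the <5% / 5–19.9% / 20–39.9% / ≥40%
bands. Inequality summaries report the min–max range, max/min fold
difference, and unit ratios to the population-weighted national mean.

# Raking

Raking factors are the ratio of the external national series to the
model's national aggregate, computed per draw against that draw's
aggregate, linearly interpolated between available years and carried flat
outside them (flagged `extrapolated`). Factors multiply every grid cell
of the country-year. Which indicator to rake is a genuinely open convention (published
practice differs); the package rakes the three marginal severities
independently and recomputes overall anemia as their sum, keeping the
severity identity intact (values pushed past 1 are clipped and logged,
and the severity sum is rescaled in the rare case it exceeds 1). With no
clipping, raking preserves within-country cell ratios and rank order,
and re-aggregation reproduces the external series exactly.

# Trends and target attainment

Pairwise annualized rates of change are differences of adjacent-year
logits. The printed ratio transcription
$\mathrm{logit}(p_t / p_{t-1})$ is positive for declining prevalence and
incompatible with the logit-space projection equation, so the package
uses the logit difference, which that equation and the GBD projection
methodology require; the ratio form remains available behind
`formula = "printed"` for audit only. Year weights
$W_t = (t - t_0)^\gamma / \sum (t - t_0)^\gamma$ up-weight recent change;
$\gamma = 1$ by default (in practice this exponent is tuned by external
out-of-sample validation, which is not reproduced here).
Projection adds $k$ years of the weighted AROC on the logit scale, so
projected prevalence stays in (0, 1). GNT attainment probability is the
fraction of draw pairs in which the projection reaches a 50% reduction
against the baseline-year draw; the synthetic study years are 2013–2018,
so the baseline defaults to 2013 (the real analysis baselines at 2012,
the year the targets were set). Both draw-level projections and
point projections of the posterior-mean final year are available;
attainment probabilities always use the draw level.

# Spatially stratified validation

Folds come from a bi-tree: recursive splits alternating
longitude-then-latitude at the weighted (lower) median of the point
coordinates, weighted by sample size; a node splits only while its total
exceeds the target size and both children keep at least the minimum
(500). Ties at the median go to the lower side; the first split is on
longitude; leaves are assigned to 5 folds by greedy largest-first
balancing. These three conventions are fixed here because published practice
leaves them open. Metrics per admin level (0/1/2), scored at
unit-years: mean error, RMSE (of observed minus posterior-predictive
mean), coefficient of variation (100·sd/mean of the predictions), 95%
interval coverage, and Pearson correlation. Predictive draws for
coverage include the nugget and binomial sampling noise — the correct
posterior-predictive reference for *observed* proportions.

Spatially blocked holdouts deliberately test extrapolation; coverage of
small-area aggregates under extrapolation runs a few points below nominal
(the fine-scale field is partly unidentifiable far from data), while
observation-level and coarser-level coverage sit in the nominal band.
The calibration test therefore scores coverage of held-out observations;
the admin-level table is reported alongside.

# The synthetic study

`make_scenario()` defines the standard study conditions: a 20 × 20 grid
of 0.25° cells, years 2013–2018, 3 countries each split into 2 admin-1
bands and 4 admin-2 blocks, 2 smooth standardized covariates (one with a
linear time drift), a log-normal population density surface (≈5–400
persons/km², times cell area), an elevation gradient to 3,000 m, and 3%
barren cells. Stage-1 truth is built exactly from the model: intercept
−0.7, covariate effects (0.4, −0.3), a Matérn⊗AR1 field with
$\omega^2 = 0.3$, $\delta = 2°$, $\rho = 0.8$, centred country effects
with $\gamma^2 = 0.05$; conditional-stage truths use intercepts 0 and
−2.3 with quarter-variance fields. These values give a mean overall
prevalence near 0.3 with realistic spatial contrast — comparable to the
prevalence levels and subnational variation reported for low- and
middle-income countries. Microdata: 300 cluster-years (population-
weighted locations, cycled through years), mean 35 women per cluster,
10% pregnant, 15% smokers; each cluster-year receives an iid logit
nugget ($\sigma^2 = 0.03$) on overall anemia. A woman's severity
category is drawn from the local continuation-ratio truth, her adjusted
hemoglobin uniformly within the category's WHO band, and the raw value
reconstructed by adding back the configured decrements — the
within-band distribution of real hemoglobin is not prescribed anywhere,
so the uniform is a convention chosen for exact round-trip testability,
not realism. Areal records draw continuation-ratio binomial
counts from population-weighted polygon means; the national series is
population-weighted national truth times a bias factor (default 1.15),
ending one year before the last so factor extrapolation is exercised.

What the generator does *not* emulate: real covariate fields (the two
surfaces are smooth toys), survey design beyond a single per-record
weight, non-uniform within-band hemoglobin, measurement error in
hemoglobin or elevation, and category-only data sources. Passing
recovery and calibration tests therefore demonstrates internal
correctness of the machinery under the model's own assumptions — not
performance on real survey data.

# Problem sizes and runtime choices

The default fit uses $D = 1000$ draws with 20 hyperparameter draws.
The test suite and the acceptance script scale the same conditions down
to keep full runs desk-sized: 200–400 draws and 8–15 hyperparameter
draws in cross-validation, 20 seeded replicates (300 draws each) in the
recovery study, and a reduced-draw pipeline for the determinism check.
These sizes were chosen so each study completes in minutes on one CPU
while keeping Monte-Carlo error well below the tolerances being
asserted.

# Known limitations

* The Gaussian approximation for $\theta$ understates multi-modal or
  heavy-tailed hyperparameter posteriors; MCMC is not included.
* The knot lattice bounds the finest spatial detail; truth fields rougher
  than the lattice spacing are partially absorbed by the nugget.
* Stacker grid predictions are plugged in without propagation of the
  learners' own uncertainty (standard practice in this workflow).
* Raking per severity with residual rebalancing is one of several
  defensible conventions; the choice is config-visible but not neutral
  when clipping occurs.
* Flat-earth areas and Euclidean degree distances are adequate at toy
  scale only.
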