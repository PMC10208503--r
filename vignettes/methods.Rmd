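---
title: "Methods: estimating causal effects on net metabolic power in cerebral palsy gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating causal effects on net metabolic power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Net metabolic power during walking — walking minus resting metabolic rate,
in watts — is markedly elevated in ambulatory children with cerebral palsy
(GMFCS levels I–III). The factors a gait laboratory measures (spasticity,
strength, selective and dynamic motor control, gait kinematics summarized
by the GDI, walking speed, body size) influence each other as well as
power, so the marginal association of any one factor with power is
confounded. `gaitcausal` estimates each factor's *total* causal effect —
direct plus mediated — which is the clinically relevant quantity when a
treatment cannot change one factor in isolation.

The chain is: a structural causal model supplies, for each exposure, the
minimal set of covariates that blocks all backdoor paths to power; a
flexible regression (BART) conditions on exactly that set; and accumulated
local effects read the exposure's dose–response off the fitted model.
Because no mediator of the exposure is conditioned on, the ALE curve
approximates the interventional mean `E[power | do(exposure = v)]` up to a
constant, provided the DAG is right and the regression fits.

## The causal model

The pinned DAG (shipped as `inst/extdata/metpower_dag.txt`, loaded by
`study_dag()`) has 11 observed variables and one latent node, the initial
brain injury, which is the shared cause of the four impairment scores and
can never be conditioned on. Sex and age drive height and mass; age,
height and mass also influence the impairments, speed, GDI and power;
walking speed is affected by the impairments and body dimensions but
itself affects only GDI and power. The arrow list is one reconstruction
consistent with the published adjustment sets and the accompanying text,
not an author-supplied enumeration, and it is deliberately shipped as data
so an alternative reconstruction can be swapped in without touching code.

Three operations matter downstream:

* `d_separated()` decides graphical independence by reachability on the
  moralized ancestral graph — linear-time, and verified in the test suite
  against a brute-force all-paths blocking oracle on hundreds of random
  graphs.
* `implied_independencies()` emits one statement per non-adjacent observed
  pair with a minimum-cardinality separating set, searched smallest-first
  inside the pair's observed ancestry (minimal separators always live
  there). Pairs separable by no observed set — e.g. two children of the
  latent injury — yield no statement, because no test could check them.
  Conditioning sets are capped at size 8; the cap binding is an error, not
  a silent omission.
* `minimal_adjustment_sets()` enumerates subsets of observed
  non-descendants of the exposure smallest-first, keeps those making
  exposure and outcome d-separated once the exposure's outgoing edges are
  removed, and prunes supersets. Exhaustive enumeration is exact and, with
  at most nine candidate covariates here, instantaneous. When no valid set
  exists the result says "not identifiable by covariate adjustment" rather
  than erroring, since that is an analysis outcome, not a bug.

Plausibility testing computes, for every implied independence, the partial
correlation of least-squares residuals over complete cases, with sex coded
0/1. The conventional cutoff |r| < 0.3 is a fixed coefficient threshold,
so no multiple-testing correction applies. Linear partial correlation can
in principle miss nonlinear dependence; that is a known limitation of the
published procedure this mirrors, not of its implementation.

## Summary scores from ordinal exams

Each exam domain rates six muscle groups bilaterally (12 items):
Ashworth 1–5 for spasticity, Kendall 1–5 for strength, 0–2 for selective
motor control. Pearson correlations of such coarse ratings are biased
toward zero, so scores use the polychoric correlation matrix: thresholds
from inverse-normal cumulative margins, then the latent bivariate-normal
correlation maximizing the cell-count likelihood (two-step ML, clipped to
±0.999). Pairwise-complete estimation can leave the matrix slightly
indefinite; it is repaired by clipping negative eigenvalues at zero and
rescaling to unit diagonal.

Scores are the first principal component applied to centered/scaled
integer item codes, for children with complete items only, standardized to
mean 0 / SD 1, with the sign chosen so that higher score tracks higher
mean rating (more spastic, stronger, better SMC). Scoring conventions the
source procedure leaves open — raw codes versus latent normal scores,
whether scores were standardized — are fixed here explicitly, as the
simplest monotone, reproducible choices.

## The BART sampler

The regression is a from-scratch sum-of-trees sampler (C++ via Rcpp, as is
usual for BART implementations), following the standard backfitting Gibbs
scheme:

* response rescaled to [−0.5, 0.5];
* tree-structure prior `P(nonterminal at depth d) = α(1+d)^(−β)`,
  defaults α = 0.95, β = 2 — strongly favouring stumps and shallow trees;
* leaf prior `N(0, σ_μ²)` with `σ_μ = 0.5/(k√m)`: `k` (default 2;
  the pipeline default is the study's selected 5) controls how hard
  individual trees are shrunk;
* noise prior σ² ~ scaled-inverse-χ²(ν, λ) with λ solved in closed form
  so a data-based σ estimate (least-squares fit, response-SD fallback)
  sits at prior quantile `q`;
* per-iteration Metropolis–Hastings structure moves with probabilities
  grow/prune/change = 0.28/0.28/0.44 (common practice; a stump can only
  grow, and the move probabilities enter the acceptance ratio), uniform
  split-variable and split-value proposals over a per-variable cutpoint
  grid (observed unique values, thinned to ≤ 100 quantiles) matching the
  uniform split-rule prior so those terms cancel; proposals creating an
  empty leaf are rejected;
* Gibbs draws of leaf values and σ² close each sweep.

Missing predictor values are handled natively ("missingness incorporated
in attributes"): every split carries a direction flag, sampled with the
split, that routes missing values left or right; informative missingness
thus becomes usable signal, which the tests verify. Categorical predictors
are one-hot coded (two-level ones as a single 0/1 column); sex is
supported this way even though it appears in no adjustment set of the
study DAG.

Chains default to 1000 burn-in plus 1000 retained draws. A fixed `seed`
makes refits bit-identical on the same machine; it cannot, of course,
replay the draw stream of any other BART implementation, so comparisons to
externally published fit statistics are tolerance-based by nature.
`bart_cv()` performs k-fold out-of-sample RMSE selection over a
configuration grid (the conventional k ∈ {2,3,5} × (ν,q) ∈ {(3,.9),
(3,.99), (10,.75)} × m ∈ {50,200} grid by default), with ties broken
toward fewer trees then smaller k; the pipeline instead defaults directly
to the study's selected set (m = 50, k = 5, ν = 3, q = 0.99).

In-sample pseudo-R² (`1 − SSE/SST` of posterior-mean predictions) and RMSE
are the reported fit metrics, matching the convention of the reference
implementation's summary output; held-out versions are available by
passing new data.

## ALE curves and effect sizes

`compute_ale()` uses K = 40 quantile bins by default (the reference ALE
convention), merging duplicate edges for discrete-ish factors, and centers
the curve so its interpolated value has count-weighted mean zero over the
sample. Rows missing the target factor are dropped for that factor's
curve; other-column missingness is routed by the model. Uncertainty bands
recompute the curve per posterior draw and take pointwise 2.5/97.5
percentiles — cheap and honest under the model. A nonparametric bootstrap
mode (resample, refit, recompute) exists for band construction but is off
by default since it multiplies fitting cost by B; the posterior band is
the package's default and the divergence is deliberate.

The effect size of a factor is the range (max − min) of its ALE curve over
the factor's central [2.5th, 97.5th] percentile window — "the middle 95%
of the sample" — evaluated at the window endpoints and interior knots of
the piecewise-linear curve. Intervals for the range come from the same
per-draw curves.

## The synthetic cohort generator

`generate_cohort()` draws age (truncated normal, 3–18 y), sex (56.2%
male), and a standard-normal latent brain-injury severity; propagates
height (quadratic growth curve, cm), mass (BMI-like, kg, multiplicative
noise), four impairment severities (shared injury loading ≈ 0.75 plus
small age/size terms), then walking speed (m/s) and GDI through saturating
tanh links, and finally net power in watts: a mass main effect (~3.5
W/kg), a linear speed cost, logistic terms in GDI, DMC, SMC and
spasticity that plateau at the extremes, an inverted-U direct strength
term, and Gaussian noise, floored at 5 W to avoid nonphysical values.
GMFCS levels are assigned by severity terciles matching the published
30.7/46.4/22.9% split. Ordinal exam items are thresholded noisy copies of
the domain severities; missingness masks are applied last, MCAR by default
at the published rates (DMC 32.1%, spasticity 18.3%, strength 17.7%, SMC
17.5%, GDI 0.6%), with a MAR option tying DMC missingness to GMFCS (the
clinically plausible direction) for robustness experiments.

Coefficients were calibrated once against the published cohort
characteristics — median GDI 71.1, median net power 124.2 W, median speed
0.79 m/s, plus the level split and missingness rates — and are frozen in
`synthetic_coefficients()`. Under the defaults the GDI effect is the
largest and strength's the smallest; this ordering is a property of the
configuration, built in by design, not an empirical finding. A fully
linear link mode exists solely so that total effects have a closed-form
path-rule value the Monte-Carlo intervention machinery can be checked
against.

Because every structural equation is closed over explicitly drawn
exogenous noise, `true_total_effect()` can clamp any factor (do-operator),
re-propagate its descendants on identical noise, and contrast mean power —
exact ground truth for validating the BART + ALE chain.

What the generator does **not** emulate: raw kinematic, EMG or
breath-by-breath signals (GDI, DMC and power enter as derived columns, as
in the cohort table contract); GMFCS IV–V children; measurement error in
the exam beyond ordinal coarsening; visit-to-visit variability (one row
per child); and any not-missing-at-random mechanism beyond the GMFCS-tied
MAR option. Tests passing on synthetic cohorts therefore demonstrate the
pipeline's internal correctness — adjustment logic, regression fidelity,
ALE/do-effect agreement — not the clinical validity of the DAG for any
real cohort.

## Numerical and design choices

* Polychoric likelihood maximized by golden-section search on [−0.999,
  0.999] with explicit boundary comparison, cell probabilities floored at
  1e−12; degenerate margins (an item entirely in one category) are an
  error naming the item.
* Partial correlations use complete cases per implication; implications
  with too few complete cases are flagged unevaluable in the report
  rather than failing the run.
* Net power conversion warns (and keeps the negative value) when resting
  exceeds walking uptake — silent dropping would bias summaries.
* The z-normalization for effect displays flips the spasticity axis so
  positive always means less severe; the transform stores one-SD-in-
  original-units metadata and is exactly invertible.
* Pipeline model grouping is data-driven: exposures whose
  {exposure} ∪ adjustment-set predictor lists coincide share one model —
  with the study DAG this yields exactly two models (GDI + speed's set;
  the four impairments' shared set). Speed, when profiled, is labelled a
  direct effect and excluded from the ranking, since its total and direct
  effects coincide in this graph.
* An exposure with no valid observed adjustment set is reported and
  skipped, never silently dropped.

## Problem sizes used in validation

The shipped tests run the analysis at the scale where its statistical
properties are demonstrable on one CPU in minutes: cohorts of 2000
children (5000 for marginal and plausibility checks), 1000 + 1000 MCMC
draws for study-configuration fits, the Friedman benchmark at n = 500 for
regression accuracy, 200 random graphs for the d-separation oracle, and
Monte-Carlo intervention samples of 20000. The full published cohort size
(2157) poses no additional computational difficulty.

## Known limitations

* Identification is by covariate adjustment only; instrumental-variable
  and front-door strategies are out of scope, as are cyclic models and
  structure learning.
* The plausibility screen is linear; a DAG wrong only in nonlinear ways
  can pass it.
* ALE effect sizes, being ranges, are biased slightly upward for factors
  whose true effect is small relative to posterior noise.
* The bundled DAG is a reconstruction; conclusions are conditional on it,
  and `run_analysis()` accepts any substitute edge list.
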