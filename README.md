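# gaitcausal

Children with cerebral palsy (CP) spend roughly two to three times more
energy walking than typically developing children. Clinicians can treat
several of the factors implicated — spasticity, muscle weakness, impaired
motor control, atypical gait kinematics — but these factors cause one
another, so naive regressions confound their effects. `gaitcausal`
implements a causal-inference pipeline for this problem, aimed at gait
analysts and clinical-biomechanics researchers working with large
observational gait-laboratory cohorts:

1. **Structural causal model.** The assumed mechanism is a directed acyclic
   graph over age, sex, height, mass, the four impairment scores
   (spasticity, strength, selective motor control SMC, dynamic motor
   control DMC), walking speed, the gait deviation index (GDI), net
   metabolic power, and a latent node for the initial brain injury. The
   package tests a DAG's plausibility against data via its implied
   conditional independencies (`X ⊥ Y | Z` checked as partial correlations
   against a conventional ±0.3 cutoff) and queries it for the **minimal
   backdoor adjustment sets** of each exposure's *total* effect: sets `S`
   of observed non-descendants of `X` with `X ⊥ Y | S` in the graph with
   `X`'s outgoing edges removed, and no proper subset sufficing.
2. **Summary scores.** Item-level ordinal exams (Ashworth 1–5, Kendall
   1–5, SMC 0–2; six muscle groups bilaterally) are summarized by the
   first principal component of the **polychoric** correlation matrix —
   ordinary PCA is biased for categorical ratings — for children with
   complete items. Oxygen uptake converts to net power as
   `P = 20.1 J/mL · (V̇O₂,walk − V̇O₂,rest)`.
3. **BART.** Each total effect is estimated by including the exposure and
   its adjustment set as predictors of net power in a Bayesian additive
   regression trees model: `y = Σⱼ g(x; Tⱼ, Mⱼ) + ε`, fitted by a
   backfitting Gibbs sampler with the `α(1+d)^(−β)` tree prior,
   `N(0, (0.5/(k√m))²)` leaf prior, scaled-inverse-χ²(ν, λ) noise prior,
   and missingness-incorporated-in-attributes routing of missing
   predictor values. The sampler is implemented from scratch in C++.
4. **Accumulated local effects.** Each factor's dose–response on power is
   read off the fitted model as an ALE curve (quantile-binned local
   prediction differences, accumulated and centered — unbiased under the
   strong collinearity of these factors), with posterior-draw uncertainty
   bands. The **effect size** of a factor is the range of its ALE curve
   over the middle 95% of the factor's sample.
5. **Synthetic cohorts.** A structural-equation generator over the same
   DAG produces cohorts with realistic marginals, the published
   missingness rates, saturating factor–power links and an inverted-U
   strength link, plus exact do-intervention ground truth — the test bed
   for the whole chain.

## Worked example

```r
library(gaitcausal)

sim <- generate_cohort(synthetic_config(n = 1000, seed = 1))
dataset_summary(sim$cohort)
#> cohort of 1000 children
#>      column median    sd    n missing
#>         age   9.38  3.59 1000      0%
#>      height 129.73 17.56 1000      0%
#>        mass  27.82 12.41 1000      0%
#>       speed   0.77  0.25 1000      0%
#>         gdi  71.06  9.03  994    0.6%
#>         dmc  83.33  9.69  684   31.6%
#>         smc   0.06  1.07  821   17.9%
#>  spasticity  -0.07  1.04  819   18.1%
#>    strength   0.04  1.06  809   19.1%
#>       power 131.89 56.29 1000      0%
#> GMFCS:  I=307  II=464  III=229

minimal_adjustment_sets(study_dag(), "DMC", "MetPower")
#> total effect: DMC -> MetPower
#>   { Age, Height, Mass, SMC, Spasticity, Strength }

report <- run_analysis(sim$cohort, seed = 42)   # ~2 min on one CPU
report
#> == causal analysis report ==
#> plausibility: PASS (max |r| = 0.0392 ; cutoff 0.3 )
#> model_A: predictors {Age, DMC, Height, Mass, SMC, Spasticity, Strength}  r2 = 0.821, rmse = 23.77
#> model_B: predictors {Age, DMC, GDI, Height, Mass, SMC, Spasticity, Speed, Strength}  r2 = 0.892, rmse = 18.45
#> effect sizes over the middle 95% of each factor (ranked):
#>    exposure   model effect_w lower upper
#>         GDI model_B     81.1  71.0  93.5
#>         SMC model_A     44.5  35.9  56.4
#>         DMC model_A     35.1  26.5  46.2
#>    Strength model_A     30.3  21.1  42.6
#>  Spasticity model_A     27.9  19.8  41.3
#> seed 42 | config c7927445 | gaitcausal 0.1.0
```

Reading the output: the data are consistent with the causal model (every
implied independence has |partial r| well under 0.3). Two BART models
suffice, because the four impairments share one adjustment set while GDI's
additionally contains walking speed. Changing a child's GDI across its
central sample range moves expected net power by ≈ 81 W — about twice any
other factor here — while the motor-control scores, spasticity and
strength have smaller effects (their ordering below GDI is within each
other's uncertainty intervals at this cohort size). Effect sizes are in
watts of net metabolic power; parenthesized columns are 95%
posterior intervals.

Per-curve detail is available via `report$curves` (plotable with
`plot()`), and `write_report(report, "report.json")` serializes
everything. A command-line wrapper covering simulation, scoring,
validation, adjustment sets, fitting and reporting ships in
`inst/cli/gaitcausal` (see `?cli`).

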