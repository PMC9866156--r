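# nichekit

Ensemble species-distribution modelling and niche-dynamics analysis for
invasion risk assessment, in R.

Biologists tracking an invasive species typically need three things from its
occurrence records and climate layers: a map of where the species could
establish (now and under future climates), an account of how that suitable
area will move and shrink or grow, and a verdict on whether the species kept
its environmental niche while invading. nichekit implements that full chain
as tested, composable functions — from occurrence cleaning to permutation
tests — together with a virtual-species simulator that provides ground truth
for validating every step.

## What's inside

**Ensemble SDM.** Eight single-model families behind one fit/predict
contract — ANN, CTA, FDA, GBM, GLM, MaxEnt-style penalized
presence–background regression, RF, SRE — trained on stratified 75/25
splits repeated 10 times (8 × 10 = 80 single models), scored by AUC
(Mann–Whitney form) and the true skill statistic

TSS(t) = sensitivity(t) + specificity(t) − 1,

maximized over observed thresholds. The top-3 families by mean (AUC + TSS)/2
form an unweighted committee whose output is the integer suitability
p ∈ [0, 1000]; the pooled-holdout max-TSS threshold c binarizes it, and
[0,c), [c,400), [400,600), [600,1000] define the unsuitable / low / moderate
/ high classes.

**Projection.** Scenario stacks are projected cellwise; class areas use the
exact spherical formula R² Δλ (sin φtop − sin φbot) with R = 6371 km;
change maps decompose gain/loss, and suitable-area centroids (area-weighted)
shift along haversine distances and bearings.

**Niche dynamics.** A PCA on the pooled background environments of the
native and invaded ranges defines a 2-D niche space; kernel-smoothed,
availability-corrected occupancies z ∝ o/e on a 100×100 grid give
Schoener's overlap D = 1 − ½ Σ|z₁ − z₂|, the COUE indices (expansion,
stability = 1 − expansion, unfilling), a lower-tailed equivalency
permutation test, directional similarity tests, and predicted-niche-occupancy
profiles.

**Synthetic ground truth.** `make_range_pair()` builds autocorrelated
climate fields, a virtual species with known Gaussian responses (two drivers
plus a flat nuisance layer), native/invaded occurrence samples, and a
controllable niche offset — so parameter recovery, test calibration, and
niche-shift detection are all checkable properties, not hopes.

## Worked example

```r
library(nichekit)

run <- run_pipeline(default_config(), seed = 1)
print(run)
#> <nk_run> seed 1 | 80 models | ensemble {GLM,ANN,MAXENT} AUC 0.904 TSS 0.689 | D = 0.838

glance(run$ensemble)
#> # A tibble: 1 × 5
#>   n_members families         auc   tss cutoff
#>       <int> <chr>          <dbl> <dbl>  <dbl>
#> 1        30 GLM,ANN,MAXENT 0.904 0.689    225

run$importance
#> # A tibble: 3 × 2
#>   variable importance
#>   <chr>         <dbl>
#> 1 env1        0.557
#> 2 env2        0.544
#> 3 env3        0.00602

glance(run$niche)[1:5]
#> # A tibble: 1 × 5
#>       D expansion stability unfilling equivalency_p
#>   <dbl>     <dbl>     <dbl>     <dbl>         <dbl>
#> 1 0.838         0         1         0         0.723
```

Reading the output: the committee of the three best families separates the
virtual species from background with pooled holdout AUC 0.90 and TSS 0.69;
the max-TSS cutoff lands at p = 225 of 1000. Permutation importance
recovers the two true driving variables (the flat nuisance layer scores
≈ 0.006). With a zero niche offset between ranges the overlap is high
(D = 0.84), the niche is fully stable (expansion 0, unfilling 0), and the
equivalency test — correctly — finds nothing to reject (p = 0.72).

Per-stage functions compose with the pipe if you want only part of the
chain, e.g. `clean_occurrences() |> thin_to_grid()`, `run_replicates()`,
`build_ensemble()`, `project_suitability()`, `niche_compare()`. Plot
methods: `autoplot()` on replicate tables, suitability maps, occupancy
grids, response curves and permutation tests.

A thin CLI wrapper ships in `inst/cli/nichekit`
(`nichekit simulate|run --config FILE --seed S --out DIR`).

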