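# sdmstack

Expert-informed stacked-generalization species distribution models (SDMs),
with a virtual-species benchmark for validating the approach against a
known truth.

## The problem

SDMs fitted to opportunistic occurrence records extrapolate into any
environmentally similar region — including regions a species cannot reach.
The motivating case is a coastal benthic species (the Japanese sea cucumber
type of setting) whose southern range limit is set by a dispersal barrier: a
large estuary's freshwater plume blocks southward larval transport, leaving
habitat south of it *suitable but unoccupied*. Occurrence-only models
predict presence there; expert range maps encode the limit, but coarsely.

`sdmstack` combines the two with stacked generalization. Four tuned
presence-background base learners produce per-cell suitability predictions

- GLM: binomial regression with second-order polynomials, AIC backward
  elimination,
- GAM: thin-plate spline smooths (3 knots), GCV smoothness selection,
- MaxEnt-style L1-penalized regression on linear/quadratic/hinge/product
  features with class-default penalties × a regularization multiplier,
- down-sampled random forest (every tree sees a balanced
  presence/background sample),

and a logistic-regression meta-learner stacks them:

```
logit P(presence) = β₀ + β₁·GLM + β₂·GAM + β₃·MaxEnt + β₄·RF [+ β₅·dist]
```

where `dist` is the distance (km) of each cell to the expert range polygon
(0 inside). The *occurrence-only* ensemble omits `dist`; the
*expert-informed* ensemble includes it. MaxEnt and RF hyperparameters are
chosen by 10-fold cross-validation: candidates in the lowest decile of
10%-omission rates, then maximum validation AUC. Evaluation uses the
continuous Boyce index, rank-based AUC, maximized TSS, exact paired
Wilcoxon signed-rank tests, 10%-omission binarization, and spherical range
summaries (area, southernmost latitude, % of suitable area inside the
expert polygon).

Because real deployments need a ground truth to validate against, the
package ships a virtual-species simulator: smooth environmental gradients
with spatial noise, a logistic true-suitability surface, Bernoulli
occupancy truncated at a latitudinal dispersal barrier, spatially biased
presence sampling, and an expert polygon equal to the occupied region plus
a commission-error buffer.

## Worked example

```r
library(sdmstack)

cfg <- virtual_species_config(seed = 1)     # 120x120 grid, barrier at 31.5 N
sim <- simulate_virtual_species(cfg)
grids <- experiment_grids(p = cfg$n_env)

res <- run_sdm_pipeline(
  sim$env, sim$presences, sim$truth$expert_polygon,
  prep = prep_config(thin_resolution = 0.1, seed = 1001),
  maxent_grid = grids$maxent, rf_grid = grids$rf,
  seed = 1, validate_single = FALSE)

res$coefficient_table
#>     predictor occurrence_only_coef occurrence_only_p expert_informed_coef expert_informed_p
#> 1         GLM               126.33           1.5e-03                23.02              0.56
#> 2         GAM                11.13           2.2e-01                 4.82              0.59
#> 3      MAXENT              -120.07           1.5e-03               -20.16              0.59
#> 4          RF                 2.75           2.6e-09                 2.79           3.5e-09
#> 5 distance_km                   NA                NA                -0.02             1.00

area_south_of(res$bin_occ, cfg$barrier_lat)   # 17350 km^2 overpredicted
area_south_of(res$bin_exp, cfg$barrier_lat)   #  3381 km^2 with expert map
```

The run shown (seed 1) overpredicts 17,350 km² of suitable habitat south of
the barrier with occurrences alone and 3,381 km² with the expert map
integrated; the southernmost suitable latitude moves from 28.05°N to
30.95°N (barrier at 31.5°N), and the share of suitable area inside the
expert polygon rises from 96.2% to 99.6%. The large opposite-signed GLM and
MaxEnt coefficients reflect their strongly correlated predictions (the
fitted sum is stable; the condition number is attached to the fit), and the
distance Wald p of ~1 despite a clearly negative effect is the
Hauck–Donner artefact of quasi-separation — the likelihood-ratio p for the
same term is < 1e-12, which is why `fit_meta()` reports both. The methods
vignette (`vignettes/expert-informed-stacking.Rmd`) discusses both points.

A narrative version of the full workflow lives in `analysis/01_simulate.R`
… `analysis/06_barrier_experiment.R` (configured by `analysis/config.yaml`,
outputs under `results/`): simulate → prepare → fit and tune the base
learners → stack both ensembles → cross-validate all six models → replicate
the barrier experiment over ten seeds.

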