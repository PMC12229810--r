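---
title: "Expert-informed stacked-generalization SDMs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expert-informed stacked-generalization SDMs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Opportunistic occurrence records and expert-drawn range maps encode
complementary information about where a species lives. Correlative species
distribution models (SDMs) fitted to occurrences alone extrapolate into any
environmentally similar region — including regions the species cannot reach.
A coastal benthic species whose southern range limit is set by a dispersal
barrier (for the motivating case, the freshwater plume of a large estuary
blocking southward larval transport) is exactly the situation where
occurrence-only SDMs overpredict: the habitat south of the barrier is
suitable but unoccupied. Expert range maps, in contrast, encode such range
limits coarsely but reliably.

`sdmstack` integrates the two sources with **stacked generalization**: four
presence-background base learners produce habitat-suitability predictions,
and a logistic-regression meta-learner combines them — optionally together
with one additional predictor, the **distance to the expert range polygon**
(0 inside the polygon, great-circle km to the nearest boundary point
outside). Two ensemble variants result:

* *occurrence-only*: meta-learner over the four base predictions;
* *expert-informed*: the same plus the distance predictor.

## The model stack

All models are fitted to a shared table of presence (label 1) and background
(label 0) rows with a shared random fold assignment — required so that
per-fold metrics are paired across models.

* **GLM** — binomial regression with linear and quadratic terms per
  predictor; backward elimination picks the AIC-minimal term set. Degenerate
  maximum-likelihood fits (separation: divergent coefficients or a
  non-converged IWLS) fall back to a lightly ridge-penalized refit, with a
  warning.
* **GAM** — additive binomial model, one thin-plate regression spline per
  predictor with basis dimension 3, smoothness selected by GCV. Constant
  predictor columns are excluded from basis construction (their smooth is
  identically zero).
* **MaxEnt-style penalized regression** — L1-penalized binomial regression
  on a MaxEnt feature expansion: standardized linear (L), quadratic (Q),
  hinge (H; forward and reverse hinges at 10 sample quantiles per
  predictor, scaled to [0, 1]), and pairwise-product (P) features.
  Per-feature penalties follow the conventional MaxEnt class defaults
  interpolated on the presence count m; the overall level is
  `rm * mean(defaults) / sqrt(m)`, with `rm` the regularization multiplier.
  Output is the inverse complementary log-log of the linear predictor,
  which is bounded in (0, 1) and monotone in it. Tuning grid:
  fc ∈ {L, LQ, H, LQH, LQHP} × rm ∈ {0.5, 1, 2, 3, 4}.
* **Down-sampled random forest** — probability forest in which every tree
  receives a bootstrap sample of the presences plus an equal-sized random
  background subsample (verified per tree from the in-bag counts), removing
  the ~30:1 class imbalance. Predictions average terminal-node presence
  fractions, so a degenerate single-node tree predicts 0.5. Tuning grid:
  trees ∈ {500, 1000} × m_try ∈ {2, ⌊√p⌋, p−1} × node size ∈ {1, 5, 10}.

**Candidate selection** (MaxEnt, RF): 10-fold cross-validation computes, per
candidate, the mean 10th-percentile omission rate (OR10: threshold at the
10th percentile of training-presence predictions, omission measured on
held-out presences) and the mean validation AUC. Candidates within the
lowest decile of omission values (ties kept — a flat omission profile keeps
everyone) are retained and the best validation AUC among them wins;
remaining ties go to the simpler model, which is listed first in the grids.

**Stacking** defaults to out-of-fold (Wolpert's scheme): each row's base
predictions come from a refit that excluded that row's fold, which prevents
strong learners from leaking training fit into the meta-learner. In-sample
stacking is available for comparison; the fit records which mode produced
its inputs. Meta inputs are used untransformed.

## Distance to the expert range

The expert polygon is stored as lon/lat rings (holes by even-odd rule). The
distance layer is 0 for cell centres inside or on the polygon and otherwise
the minimum haversine distance (sphere radius 6371 km) to the polygon
boundary densified to a vertex spacing ≤ 0.05° — the densification bounds
the nearest-point discretisation error to well under a cell width at the
scales used. Distances are in km, so the meta-coefficient is per km.
Multipolygon parts compete; the nearest wins.

## Evaluation

* **Continuous Boyce index**: 101 moving windows of width one-tenth of the
  pooled suitability range; per window, the ratio of the presence fraction
  to the background fraction (windows with no background mass dropped);
  the index is the Spearman correlation of that ratio with the window
  midpoint. Window membership is computed on the midpoint-index scale,
  where the alignment of the sample extremes with window edges is exact.
  Runs of tied ratios are collapsed before the correlation
  (`rm_duplicate = TRUE`, the convention of the standard continuous-Boyce
  implementations) — without it, the long zero-presence runs produced by a
  sharply ranked model cap the index far below 1. Two caveats the tests
  make explicit: with heavily overlapping windows the null index is noisy
  (|B| of several tenths is compatible with no skill at n = 1000), and the
  index is *not* invariant under non-linear monotone transforms of
  suitability, because windows are equal-width on the value scale. The
  exact antisymmetry B(−x) = −B(x) holds for the uncollapsed profile.
* **AUC**: rank-based (Mann–Whitney), ties counted ½.
* **TSS**: max over thresholds (midpoints of sorted unique values) of
  sensitivity + specificity − 1.
* **Paired Wilcoxon signed-rank test**: exact two-sided p by dynamic
  programming over the signed-rank generating polynomial (zeros dropped,
  midranks for ties; exact up to n = 25, normal approximation with tie
  correction beyond). Verified against full 2^n enumeration in the tests.
* **Binarization**: the 10% omission threshold is the ⌈0.1·n⌉-th smallest
  training-presence suitability; cells with suitability ≥ threshold are
  suitable (threshold-inclusive).
* **Range summaries**: suitable area by the spherical-strip formula
  R²·Δλ·(sin φ_top − sin φ_bot); southernmost suitable cell-centre
  latitude; percent of suitable area whose cell centres fall inside the
  expert polygon.
* **Cross-validation**: presences and background are partitioned into 10
  random folds (not spatially blocked — a deliberate scope choice); all six
  models are trained on 9 folds and scored on the held-out fold, with the
  held-out background rows as the Boyce expectation sample.

Wald p-values are reported for the meta-coefficients, but the package also
reports likelihood-ratio (drop1) p-values, and the barrier experiment uses
the latter for the distance term. The reason is statistical, not cosmetic:
when the expert polygon has no omission error — which is *always* true for
the simulated species, whose polygon contains every occupied cell by
construction — positive distance almost perfectly predicts absence. The
distance MLE then drifts toward −∞ and the Wald statistic collapses
(Hauck–Donner effect) even though the evidence for the term is
overwhelming; the likelihood-ratio test remains valid. For the same reason
the *magnitude* of the simulated distance coefficient is near-degenerate
and only its sign is meaningful.

## The virtual species

The simulator generates everything the workflow needs, so the pipeline is
testable offline with a known truth:

* **Grid**: 118–130°E × 28–40°N at 0.1° (120 × 120 cells), emulating the
  Yellow/East China Sea shelf; barrier at 31.5°N (the Yangtze-estuary
  latitude).
* **Environment**: 4 layers, each a rotating mix of the latitudinal and
  longitudinal gradients plus spatially autocorrelated noise (white noise
  smoothed with a Gaussian kernel of 5 cells; weight 0.6 against the
  gradient), standardized to mean 0, sd 1. The rotation keeps layer
  pairwise correlations moderate, so the |r| > 0.7 screen usually retains
  all four.
* **Truth**: suitability = logistic(b₀ + Σβⱼxⱼ + Σγⱼxⱼ²) with defaults
  b₀ = 0.5, β = (1.6, −1.2, 0.8, 0), γ = (−1.0, −0.6, 0, 0) — chosen once
  to give a broad northern suitable region, a realistic prevalence
  (~0.35–0.4), and a substantial band of suitable habitat south of the
  barrier (several hundred cells), without which the headline contrast
  would be vacuous (the generator warns in that case).
* **Occupancy**: Bernoulli(suitability) north of the barrier, 0 south —
  Bernoulli rather than thresholded so presences span the suitability
  gradient as real data do.
* **Presences**: 300 records drawn without replacement from occupied cells
  with weight suitability^bias × a coastal kernel (effort decaying eastward
  from the mainland coast with scale one-third of the longitudinal extent),
  jittered within cells — emulating spatially biased opportunistic
  sampling.
* **Expert polygon**: the exact rectilinear outline of the occupied cells
  dilated by 50 km (commission error, emulating the coarseness of
  IUCN-style maps). The dilation is an exact per-row morphological
  operation (the admissible column offset per latitude-row offset is
  solved from the haversine formula), validated against a brute-force
  nearest-distance oracle in the tests. At buffer 0 the polygon area equals
  the summed cell areas exactly.

What the simulation does *not* emulate: omission error in the expert map
(every presence lies inside the polygon — see the Wald/LRT note above),
ocean-current dispersal, temporal dynamics, and observation-level
coordinate error beyond within-cell jitter. Passing the barrier experiment
therefore shows that the machinery integrates an accurate range limit
correctly; it does not certify behaviour under an *inaccurate* expert map,
which the motivating literature flags as the key practical caveat.

## Problem sizes and numerical choices

The packaged experiment uses the 120 × 120 grid with 300 presences and
10,000 background points, 10 folds, and compact tuning grids
(MaxEnt {LQ, LQH} × rm {1, 2}; RF 500 trees, m_try 2, node size {1, 10}) so
that a ten-seed replication completes in minutes; the full conventional
grids remain the package defaults for single runs. Occurrence thinning in
the experiment uses the grid's own 0.1° resolution — thinning at the
environmental resolution, as in standard practice (the `prep_config()`
default is 0.05°, matching 3-arcmin layers). Background sampling is
uniform over calibration cells, without replacement when the area has at
least `n_background` cells (with replacement otherwise); background may
coincide with presence cells, the standard presence-background design.
Collinearity screening drops, among the offenders of any |r| > 0.7 pair,
the predictor with the highest mean absolute correlation, never a member of
the user's `keep_list` — a reproducible stand-in for expert choice among
correlated predictors. Thinning keeps the first record per cell, making it
deterministic and idempotent without a seed.

Rasters are handled in a lightweight lon/lat grid container written to
ESRI ASCII (.asc) interchange files; polygons round-trip through GeoJSON.
All great-circle computation uses the haversine formula on a 6371-km
sphere; a one-degree meridian arc is 111.19 km, which anchors several
tests.

## Known limitations

* Random (not spatial-block) cross-validation matches the motivating
  workflow but optimistically scores spatially autocorrelated data.
* The meta-learner inherits the identifiability problems of its inputs:
  strongly correlated base predictions (GLM vs MaxEnt is common) produce
  large, opposite-signed coefficient pairs whose sum is stable; the
  condition number of the design is attached to every fit and a warning is
  raised when it is extreme.
* The distance predictor is a straight-line (great-circle) distance;
  network-constrained distances (rivers, coastlines) are out of scope.
* Per-fold Boyce on small held-out folds is noisy; fold-to-fold standard
  deviations of several tenths are expected and mirror the motivating
  study's reported spreads.
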