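---
title: "Modelling the competitive ceiling on lagomorph body size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the competitive ceiling on lagomorph body size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagoceiling)
```

## The scientific question

Wild continental lagomorphs top out near 5 kg, despite the clade's ecological
success and despite domestic and insular relatives showing that much larger
bodies are developmentally reachable. This package implements a quantitative
test of one explanation: that the *smallest* co-occurring ungulate-type
herbivore sets an upper bound on lagomorph body size through exploitative
competition. The pipeline has three legs: (1) a modern biogeographic leg
(per-ecoregion guild extrema and a boosted-tree model), (2) an energetic leg
(allometries of density and metabolic rate composed into local-population
energy use), and (3) a deep-time leg (per-bin fossil series and AICc model
selection with uncertainty propagation).

## Local-population energy use

Basal metabolic rate and local population density are modelled as power laws
of body mass, fitted on the log10 scale by phylogenetic GLS. Their
composition gives the energy used by a local population,
`log10 E = alpha + beta * log10 M`. Two properties drive everything
downstream:

* the two guilds' lines cross at an equilibrial mass `M*`
  (`equilibrial_mass()`), with `M* ≈ 6.3 kg` under the package's default
  generating parameters (metabolic scaling shared, density falling much more
  steeply in lagomorphs);
* because the ungulate line is shallower, the energy-equivalent lagomorph
  mass for an ungulate of mass `m` (`energy_equivalent_mass()`) changes by
  the factor `beta_ung / beta_lag` per log unit of `m` (0.375 by default),
  so even an eightfold rise of the smallest ungulate barely moves the
  implied lagomorph ceiling.

Uncertainty on both quantities is propagated to first order (delta method)
from the parameter covariances of the two fits, treating the fits as
independent. With zero input variance the intervals collapse to points,
which the tests verify.

## The PGLS engine

`pgls_fit()` maximizes the full Gaussian likelihood of a linear regression
whose error covariance is `sigma2 * C(lambda) + diag(w)`, where `C(lambda)`
is the Brownian tip correlation of a time-calibrated tree with off-diagonal
entries scaled by Pagel's lambda, and `w` are optional known per-species
variances (used for intraspecific sampling error of species means). Choices
a maintainer should know:

* **lambda** is estimated by bounded scalar optimization on [0, 1]
  (tolerance 1e-6) with explicit evaluation at the grid {0, 0.25, 0.5,
  0.75, 1}, so the reported optimum always dominates the boundary values.
  The likelihood is full ML, not REML; at the sample sizes exercised here
  the difference is immaterial, and ML keeps the lambda profile simple.
* For ultrametric trees without measurement error the lambda transform
  preserves the eigenvectors of `C`, so one eigendecomposition per tree
  serves every candidate lambda; this is what makes the 500-replicate
  calibration studies cheap. With per-species weights the dense
  Cholesky path is used and `sigma2` is profiled numerically.
* The **parameter covariance** uses the degrees-of-freedom-corrected
  residual variance (`n/(n-2)`, as in ordinary regression practice), and
  intervals use t quantiles, while `sigma2` itself is reported as the ML
  estimate. Plug-in ML covariances are anti-conservative at moderate n; the
  package's calibration test (500 simulated 200-tip datasets) shows 95%
  slope intervals covering the truth 93-97% of the time under this
  convention.
* **Confidence bands** (`pgls_confband()`) are parameter-only by default;
  `include_residual = TRUE` widens them to prediction bands. Both are
  provided because published figures rarely state which is shown.
* **New-tip prediction** (`pgls_predict_newtip()`) is the conditional
  multivariate-normal mean given the observed residuals of relatives, with
  variance combining the residual variance, the conditioning reduction, and
  the parameter-uncertainty term. In the limits it reduces to the
  fixed-effect line (no covariance) and to the observed value of a zero-
  distance twin.

## Fossil body masses

`species_means()` collapses specimen records to species means on log10
scale; `fit_mass_model()` regresses species-mean log mass on a dental or
mandibular dimension with weights `pooled_within_species_var / n_i`, and
reports predictive accuracy as mean absolute percent error from
leave-one-out refits. Fossils with a phylogenetic placement use
conditional-normal prediction; unplaced fossils (the conservative default)
use the fixed-effect line with full prediction variance. Multiple estimates
per taxon combine by inverse-variance weighting. All masses stay on the
log10 scale internally — pseudo-replicates draw normal deviates on that
scale — and no smearing correction is applied on back-transformation, since
estimates are consumed on the log scale rather than averaged arithmetically.

## The time-series stage

Ages are Ma before present (larger = older). The grid is 29 contiguous
1.5-Myr bins from 43.5 Ma; bins are indexed from 0 (oldest). Binning
assigns a boundary age to the older of its two bins, so every age maps to
exactly one bin. Records whose locality age range exceeds 4.2 Myr are
excluded (strictly "exceeding": exactly 4.2 is kept). Point-estimate runs
date each record by its locality midpoint age; pseudo-replicates draw one
uniform age per locality, shared across that locality's taxa so co-occurrence
is preserved. Presence is range-through: a taxon occupies every bin between
its first and last occurrence bins. Per-bin series are then: guild extrema
over present taxa; glires sampling probability `k/n` (sampled vs
range-through genera) on the empirical-logit scale
`log((k+0.5)/(n-k+0.5))`, which stays finite when every genus is sampled;
d18O records averaged within bins; hypsodonty interpolated linearly to bin
midpoints with no extrapolation; and the competitive ceiling, which is the
energy-equivalent mass of the bin's minimum perissodactyl in the 37.5-24.0
and 15.0-1.5 Ma regimes and the minimum artiodactyl mass in 24.0-15.0 Ma.
Regime windows are configuration data (`default_regimes()`); identifying
them from the trajectories is a judgement call the package does not
automate.

## Model selection

Eleven candidate regressions of per-bin maximum lagomorph mass are compared:
five single-predictor models (ceiling, minimum perissodactyl, d18O,
hypsodonty, glires sampling) and the six pairs combining the ceiling or the
perissodactyl minimum with each remaining predictor. Each model is a
two-pass least-squares fit: the autocovariate is the *previous bin's
residual from a first pass that ignored autocorrelation*; the oldest
retained bin is dropped, and a bin following a gap uses the nearest
available older residual. The log-likelihood is the Gaussian profile
likelihood and `k` counts intercept, predictors, autocovariate and residual
variance, so `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`. All models are fitted
on the identical complete-case row set inside the 37.5-1.5 Ma window (the
most recent bin is excluded), which AICc comparability requires. The second
pass is ordinary least squares: once the lagged residual enters as a
regressor, the stated model has no remaining error structure to model, so a
GLS machinery would add nothing. Pseudo-replicates derive per-replicate
sub-seeds from the master seed by counter, so enlarging `n_reps` never
reshuffles earlier replicates; mass draws include the full reported
standard error (residual plus parameter terms), with the point estimate as
the mean.

## The ecoregion stage

`guild_extrema()` reduces a per-ecoregion species list to the largest
leporid and the smallest ungulate-type herbivore, excluding omnivorous and
semiaquatic taxa. `skewness_g1()` is the sample-size-adjusted
Fisher-Pearson moment coefficient; by default the package computes it on
log10 species masses (mass distributions are analysed on the log scale
throughout), with the raw scale available by simply passing raw values.
`brt_model()` is a two-pass boosted regression: fit, form the
neighbour-mean-residual spatial autocovariate from the adjacency list
(single pass, no fixed-point iteration — the residual autocovariate method
is defined from the initial fit), then refit with the autocovariate
included. Boosting is delegated to xgboost with tree depth 3, learning rate
0.005 and row subsampling 0.75, the number of trees chosen by k-fold
cross-validation; relative influences are normalized split gains (summing
to 100%) and partial dependence is grid-averaged prediction. Ecoregions
with no neighbours get autocovariate 0 with a warning.

## What the synthetic data emulate — and what they do not

The generators produce: pure-birth (Yule) ultrametric trees (the simplest
generator exercising lambda-GLS; no extinction or rate shifts); traits with
multivariate-normal residuals `sigma2 * C(lambda)` and log-uniform masses
(matching the log-linear allometric domain); fossil records whose per-bin
clade extrema equal specified trajectories, with uniform-in-bin locality
ages, symmetric bounded age errors, and normal log-mass errors; and
ecoregion tables with a grid adjacency and optional neighbour-smoothed
spatial noise. Two realism decisions matter for interpreting the tests.
First, extremum-defining taxa are well-sampled (occurrences in every bin of
their range) and background taxa lie within 0.05-0.5 log units of the clade
extremum: real assemblages carry several species near a guild boundary, so
an age-resampled bin should never see its maximum collapse by an order of
magnitude. Second, in `ceiling_scenario()` the null proxies (d18O,
hypsodonty) and the artiodactyl deviation are *stationary* smoothed noise
rather than random walks: over 24 bins a random walk routinely
chance-correlates with a trending response, which would make the scenario
test spurious-regression behaviour instead of the ceiling signal it is
meant to carry. Consequences: passing tests show the pipeline recovers
known structure under these idealized conditions; they do not show
robustness to taxonomic error, preservational bias varying with mass, or
proxy series that genuinely trend with the predictors — all properties of
real data the generators deliberately omit.

Default study conditions: 1.5-Myr bins from 43.5 Ma; locality age
half-widths up to ~0.5 Myr (well under the 4.2-Myr exclusion rule, matching
the reported median Neogene locality uncertainty of about a megayear); mass
standard errors of 0.04-0.05 log units; energy lines (2.8, -1.2) and
(2.2, -0.45), crossing at 6.31 kg; trait residual SD 0.15 log units with
lambda 0.5. Test and acceptance runs use 200-500 replicates where the
analysis prescribes 500 or 1,000; these sizes give Monte-Carlo error well
inside the asserted bands while keeping the default check suite fast.

## Numerical choices and degenerate inputs

Ties at bin boundaries go to the older bin; regime lookup happens at bin
midpoints, which never sit on regime edges when windows align with bin
boundaries. A numerically perfect first-pass regression zeroes its
residuals before the autocovariate pass, so the autocovariate coefficient
is exactly 0 rather than a fit to rounding noise. Zero-variance fits
produce zero-width bands and exact predictions. Constant predictors,
constant responses, empty trajectories, dangling adjacency ids, and
out-of-range lambdas raise classed errors (`lagoceiling_invalid_argument`,
`lagoceiling_degenerate_design`, `lagoceiling_insufficient_data`, ...).
Replicates that fail for data sparsity are counted and reported, never
silently dropped.

## Known limitations

Only Pagel's lambda is supported as a covariance transform (no OU or
kappa); the energy model is strictly log-linear; regime boundaries are not
detected automatically; synonymy curation and GIS covariate extraction are
upstream of the package; and the boosted-tree stage inherits xgboost's
behaviour for its tree-growing details, which differs in minor ways from
other gradient-boosting implementations even at identical nominal
hyperparameters.
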