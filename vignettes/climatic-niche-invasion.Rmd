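---
title: "Niche overlap and ensemble climatic-suitability change for invasive amphibians"
author: "climniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Niche overlap and ensemble climatic-suitability change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climniche)
```

## The problem

An amphibian introduced outside its native range spreads along climatically
favourable corridors, and conservation planners need to know three things:
whether the invader's climatic niche overlaps the niches of sensitive native
species, where climate will remain or become suitable for it by the late
21st century, and whether the protected-area network — in particular the
sites explicitly designated for the native species — will still cover
favourable conditions then. `climniche` implements that full analysis as a
pipeline of small, testable steps, and ships a virtual-species simulator so
every step can be validated against a known truth.

The analysis operates on a grid of 10 × 10 km cells carrying five
environmental layers: maximum temperature of the warmest month (BIO5, °C),
minimum temperature of the coldest month (BIO6, °C), annual precipitation
(BIO12, mm), altitude (m) and slope (degrees). Temperature extremes, water
availability and relief are the abiotic axes that matter most for
Mediterranean amphibians.

## Niche overlap in a shared principal-component space

All five variables are centred and scaled (each has its own units, so a
correlation PCA is the only defensible choice) over the *whole* study area
— both the native and the invaded region pooled. Calibrating on the full
background rather than on occurrences puts every species into one common
environmental space; comparing species-specific PCAs would conflate niche
differences with axis differences. A flag allows occurrence-calibrated PCA
for users who prefer it. Standard deviations use the sample (n − 1)
convention throughout, matching the standardization used later for
suitability change.

Each species' environmental space is delimited as the *maximum convex
polygon* (convex hull) of its occurrences projected on the first two
components, and niche overlap is the area of intersection of two hulls,
reported both in PC units² and as a fraction of each species' own hull
area. Reporting both denominators keeps the measure interpretable whichever
species is the reference. Niche shift of an invading population is
diagnosed by the number and fraction of its occurrences falling *strictly*
outside the native-range hull; points on the boundary count as inside,
because "outside the native environmental space" reads as strict
exteriority.

Numerical choices: hull vertices are stored counter-clockwise; intersection
uses Sutherland–Hodgman half-plane clipping (exact for convex polygons) and
the shoelace formula; the point-in-hull test uses a tolerance of 1e-9
scaled to the hull size so floating-point boundary points are not
misclassified; collinear point sets raise a degenerate-hull error rather
than returning a zero-area polygon.

## Ensemble distribution models

Climatic suitability is modelled from the three climate predictors only
(BIO5, BIO6, BIO12). Relief enters the niche-overlap PCA but not the
projection models: altitude and slope do not change by 2070, and letting
static covariates anchor a "climatic" suitability score would dilute the
climate signal the projection is meant to isolate. A configuration flag can
add relief as static covariates if desired.

For each species, `buildEnsemble()` runs R = 10 replicates. Every replicate

1. draws an environmentally stratified pseudo-absence sample of *equal size
   to the presences* (for presence-only data), allocated across
   ecoregion-like strata proportionally to stratum background size with
   largest-remainder rounding, excluding presence cells — or uses the
   explicit absences when the data are atlas surveys;
2. splits the sample 70 % / 30 %, stratified by the presence label so both
   classes appear on both sides;
3. fits five model families on the training part — GLM (logistic with
   quadratic terms), GAM (thin-plate smooths, REML), MARS
   (forward/backward hinge-basis selection on a logistic link), GBM
   (gradient-boosted shallow trees) and FDA (linear discriminant analysis
   on the hinge basis) — and scores each on the held-out part by AUC.

Pseudo-absences are *re-drawn* every replicate rather than merely re-split:
re-drawing propagates background-sampling uncertainty into the spread of
the replicated AUCs, which is what the replication is for. The AUC is the
rank (Mann–Whitney) statistic with ties counting one half; it is invariant
under any monotone rescaling of the scores, which is why members of very
different families can be compared with it.

Members with test AUC ≤ 0.7 are dropped (strictly greater than 0.7
retains; the threshold is a skill floor, not a target) and all surviving
members across all replicates are pooled into one consensus whose weights
are the raw test AUCs normalized to sum to one. Raw AUC — not AUC − 0.5
rescaled — is used deliberately: the ensemble is a weighted average "using
AUC values as model weights", and since all retained AUCs exceed 0.7 the
practical difference is a mild flattening of weights.

Hyperparameters are fixed in the configuration (GAM basis size 5, GBM
depth 3 / learning rate 0.1 / 80 rounds, three interior hinge knots per
variable for MARS and FDA) rather than tuned: reproducibility of the
pipeline matters more here than squeezing out the last point of AUC.

Transferability of a native-range model to the invaded range is assessed by
predicting the invaded region, scoring invaded presences against an
equal-size stratified pseudo-absence sample from that region's background,
and reporting the AUC.

## Standardized climatic-suitability change

Future stacks are built by adding per-variable deltas to the current
climate (relief unchanged) and averaging several climate-model variants
cellwise into a single layer per predictor and scenario. Two scenarios are
carried: an optimistic (RCP 2.6-like) and a pessimistic (RCP 8.5-like)
pathway.

Raw ensemble scores live on species-specific 0–1 scales, so changes are
measured in *standard scores*: z = (score − mean) / sd, where mean and sd
come from the **current** prediction — future maps are standardized with
current-map statistics, so Δz counts how many current-scale standard
deviations a cell moves. The reference population is all cells of the
projection region (the invaded-range study area); the sample sd (n − 1) is
used. Δz is computed on masked cells only: the occupied cells of each
sensitive species, the invader's currently invaded cells, and — under a
conjectural long-distance-dispersal scenario — the *potential range*, the
union of all cells where any sensitive native species is recorded.

Cells are then split by protection regime: outside the network, generic
protection, and sites explicitly targeted at the focal species. Sites
targeted at *other* species count as generic protection (the groups
partition the cells; a flag could relax this, but a partition keeps the
cell accounting auditable). Each group is summarized by its 5, 25, 50, 75
and 95 % quantiles with linear interpolation between order statistics
(quantile type 7, the convention of mainstream box-plot software, whose
whiskers these quantiles feed).

Group comparisons use a paired t-test when the two vectors share a
cell-to-cell pairing (the same cells under two scenarios) and a Welch
two-sample t-test otherwise (inside vs. outside protection are different
cell sets, so "paired" would be meaningless). p-values are two-sided and
deliberately uncorrected — the pipeline logs the number of comparisons so
a reader can apply any correction they prefer.

## What the simulator emulates — and what it does not

`generateEnvStack()` builds each layer as Gaussian-kernel-smoothed white
noise (circular FFT convolution) rescaled to realistic ranges, with BIO6
and BIO12 partially coupled to altitude so the world has the
colder-and-wetter-uphill structure real landscapes have, and BIO5 > BIO6
enforced cellwise. The correlation length (default 50 km) is the simplest
controllable surrogate for the smoothness of interpolated climate
surfaces. Virtual species follow product-Gaussian responses, so the true
suitability surface is known everywhere; occurrence sampling mirrors the
two real designs (presence-only records drawn proportionally to
suitability; atlas cells surveyed uniformly with Bernoulli presence).
Strata are Voronoi regions around random seeds; the protected network is
grown as compact patches to a 20 % coverage quota with a 5 % targeted
subset, emulating the coverage of the real network.

The simulator does **not** emulate coastlines, real geography, map
projections, spatial sampling bias, observation error in the predictors,
or biotic interactions. Passing tests therefore demonstrate that the
*method* recovers known niches, transfers across regions, and tracks the
direction of climate shifts under clean conditions — not that any
particular real-world inference is correct.

One subtlety the tests respect: the twin-region (identical niche, two
regions) checks are only valid when the two regions offer the same
environment. With long-range climate fields on a small grid the regions
realize genuinely different climate envelopes and hull overlap saturates
below its theoretical value for reasons unrelated to the method. Those
checks therefore use a 20 km correlation length on an 80 × 80 grid, where
disjoint regions are climatically exchangeable.

## Study conditions and problem sizes

The default configuration (`defaultConfig()`) is the synthetic study: a
100 × 100 grid of 10 km cells, an invader with 150 native-range and 80
invaded-range presence-only records, two native species with 800 atlas
cells each, 10 strata, 20 % / 5 % protection coverage, six climate-model
variants per scenario, deltas of +1.5 °C / −50 mm (optimistic) and
+4.5 °C / −150 mm (pessimistic), and ensembles of all five families with
10 replicates. The test suite exercises the same machinery at reduced
sizes (24–80 cell grids, 2–3 replicates) so the full suite stays fast; the
parameter-recovery checks run at the full 100 × 100 / 500-record / 10-seed
scale.

```{r example, eval = FALSE}
res <- runPipeline(defaultConfig(baseSeed = 1), outDir = "run1")
res$niche$overlaps          # hull intersection table
aucSummary(res$ensembles$invader)
head(res$changes$summary)   # Figure-style regime quantiles
```

## Known limitations

* Convex hulls are sensitive to extreme occurrences; a single outlying
  record can inflate a species' environmental space. The package reports
  point-level `pointsOutside()` alongside area overlap for this reason.
* Pseudo-absence AUCs are not comparable across datasets or regions; they
  rank models fitted to the same data, which is the only use made of them.
* The long-distance-dispersal potential range is a scenario, not a
  forecast: it assumes the invader can reach every cell where a native
  species occurs.
* Additive climate deltas ignore changes in inter-variable covariance; the
  simulator's futures shift means without reshaping the joint
  distribution.
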