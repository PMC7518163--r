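---
title: "Methods: presence-only ensemble SDMs and their validation by virtual species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only ensemble SDMs and their validation by virtual species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the modelling choices: the
procedure and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The modelling problem

The package targets presence-only distribution modelling of mobile marine
species on a regular geographic grid. The data model is deliberately
austere: an `EnvStack` of aligned predictor layers with a shared nodata
mask, and an `OccurrenceSet` of dated, sourced sighting records. All
spatial semantics flow from one convention — cells are half-open boxes
indexed row-major from the north-west corner, and a point on a shared edge
belongs to the cell to its east/south. Every operation that touches
coordinates (resampling, clipping, extraction, thinning, background
sampling) uses that single rule, which is what makes the brute-force
containment oracles in the test suite decisive.

Key assumptions:

* inputs are already in geographic WGS84 — there is no projection engine;
* predictors are static seasonal climatologies; interannual trends are
  deliberately averaged away;
* occurrence records are usable as presences after grid-cell thinning,
  i.e. residual effort bias is tolerated, not modelled.

## Stage-by-stage choices

**Collinearity screen.** `vifScreen()` computes `VIF_j = 1/(1 − R_j²)`
with ordinary least squares and retains variables strictly below the
threshold (default 3). The comparison is strict because the retention rule
is phrased as "less than three"; a perfectly collinear column (R² = 1) is
reported as infinite and dropped rather than crashing the regression. The
pipeline screens on a deterministic sample of up to 2 000 valid cells —
the VIF of smooth fields is a property of the whole surface, and 2 000
cells estimate it amply.

**Thinning.** One record per cell of the analysis grid, keeping the first
record in input order. Distance-based thinning was the alternative;
cell-level deduplication at the predictor resolution is the minimal rule
that removes within-cell pseudo-replication, and the deterministic
keep-first tie-break makes reported counts reproducible.

**Pseudo-absence designs.** Equal-to-presence counts for ANN, CTA, GBM,
RF and SVM; a fixed 1 000 for GLM and MARS; 10 replicates each; points at
cell centres of valid cells, drawn uniformly without replacement. Two
open points were settled as follows: GBM is grouped with the equal-count
families (it is fitted by a regression-style loss, but the presence-
matched design is what its count pattern calls for), and cells holding a
presence are excluded by default (`excludePresenceCells = TRUE`) because
sampling contradictory labels into the background adds noise with no
compensating benefit; the flag exists for strict emulation of samplers
that draw anywhere. Because background points are only ever placed on
valid cells, the drawn counts are exact — designs that lose points to
invalid cells after the fact are documented behaviour of other
implementations, not imitated here.

**Learner families.** The seven families are bound to standard
implementations (`nnet`, `rpart`, `xgboost`, `stats::glm`, `ranger`,
`e1071`); MARS is a compact in-package forward-stagewise hinge-basis
expansion calibrated by one binomial GLM, because no reliable MARS
dependency is available. Hyperparameter defaults are the algorithms'
textbook forms (ANN: 5 hidden units, weight decay 0.01; CTA: cp 0.01;
GBM: 100 rounds at learning rate 0.1, depth 3; RF: 500 probability trees,
mtry = ⌊√p⌋; SVM: radial kernel, cost 1, Platt calibration; MARS: ≤ 11
terms, 10 candidate knots per variable); all are overridable per family
through the config. Every fit is deterministic given its seed.

**Evaluation.** Rank-based (Mann–Whitney) AUC with midranks for ties, so
constant scores give exactly 0.5. Repeated stratified holdout at 70/30
with 10 repeats; repeat *i* evaluates against pseudo-absence replicate
((i − 1) mod n_draws) + 1, so the default 10 repeats exercise all 10
draws with one fit each. The alternative — a full 10 × 10 cross of
repeats and draws — multiplies cost tenfold without changing the mean
AUC estimate appreciably.

**Ensemble.** Families with mean AUC *strictly* above 0.7 are averaged
with equal weights — the AUC acts as a gate, not a weight. Uncertainty is
the per-cell *population* variance (divide by n) across the included
family maps: n is as small as 2, and the quantity is a descriptive spread
of the specific members at hand, not an estimate of a superpopulation
variance. Variance across the family *means* (not across all replicate
models) is what "agreement among algorithms" means here. With a single
included family the uncertainty map is undefined and refused rather than
silently zero.

**Importance and partial effects.** `I_v = 1 − Cor(P_f, P_v)` with
Pearson correlation (Spearman available), averaged over 10 permutations
with a recorded seed — a single shuffle is the textbook form, but
averaging suppresses Monte-Carlo noise at negligible cost. Sampling can
push an individual correlation below zero (index above 1); indices are
clamped to [0, 1] and flagged. If predictions are constant the
correlation is undefined and the index is reported as 0 with a warning.
Partial effects evaluate `partialGrid = 50` evenly spaced points spanning
the observed range, others held at their means; the ensemble curve equals
the mean of the included families' curves by linearity. The evaluation
table for pipeline diagnostics is the presences plus the first replicate
of each distinct background design, deduplicated by cell and capped at
`importanceRows = 500` deterministically sampled rows: correlation
estimates stabilise well before that (SE ≈ 0.045), and diagnostics cost
scales linearly in rows times permutations times member models.

## What the virtual species emulates — and what it does not

`synthEnvStack()` builds the eight-layer marine roster (bathymetry,
slope, dist_shore, chl_a, sst, salinity, uo, vo) on a 120 × 100 cell grid
at 0.083° with a 12-column western land band. sst is a north–south
gradient (26 → 12 °C) with smoothed noise; dist_shore is the chamfer
distance to the land mask in km; the remaining layers are Gaussian random
fields built by separable kernel smoothing of white noise (correlation
lengths 4–8 cells) and rescaled to oceanographically plausible means and
spreads. chl-a is floored at 0.02 mg m⁻³.

The default virtual species is a **habitat specialist**: suitability is
the product of a Gaussian response in sst (optimum 20 °C, breadth 1.2 °C)
and in chl-a (optimum 0.8 mg m⁻³, breadth 0.15 mg m⁻³), rescaled to
maximum 1; the other six layers are pure noise with respect to the
species. The breadths were fixed from the generator's own geometry: with
presences sampled proportional to suitability and background uniform, the
theoretical ceiling on AUC is P(S_presence > S_background), ≈ 0.91 for
these breadths versus ≈ 0.75 for a broad generalist (sd 2.5 / 0.35). The
recovery tests presume a strong-signal regime, and the specialist is the
design point that provides one; the generalist remains one constructor
call away.

Presence sampling draws cells with replacement (repeat sightings of good
habitat are the norm in opportunistic data — and thinning then has work
to do), places each record uniformly within its cell, and dates it
uniformly within the season window. Optional coast-biased effort
multiplies the sampling weight by exp(−distance/λ).

What passing recovery tests do **not** show about real data: the
simulator has no observation error in the predictors, no temporal
mismatch between sighting dates and climatologies, no spatial
autocorrelation in the *sampling* process beyond the optional coastal
decay, and its noise layers are genuinely independent of the species —
real "noise" predictors are usually confounded with the true drivers.
Recovery under simulation is a necessary check of the machinery, not a
validation of any particular real-world map.

## Numerical and degenerate-input conventions

* Nearest-neighbour resampling looks up the *target cell centre* in the
  source grid; disjoint extents are an error, partial overlap yields
  nodata outside the source.
* Seasonal means ignore nodata months per cell; a cell is nodata only if
  every contributing month is.
* Rasters round-trip bit-exactly: float64 GeoTIFF samples, `%.17g` text
  in ASCII grids, and a nodata sentinel (−3.4 × 10³⁸) far outside any
  physical range.
* Extraction flags out-of-extent and invalid-cell points per point
  instead of erroring.
* The MARS forward pass stops when the relative RSS improvement drops
  below 10⁻⁶ or the term budget is reached; rank-deficient final bases
  have their NA coefficients zeroed.
* One global seed fans out to per-stage seeds by fixed offsets, so any
  stage can be re-run in isolation bit-identically; replicate r of a
  pseudo-absence design uses seed + r.

## Problem sizes used by the shipped tests

The validation suite runs the full seven-family pipeline at the default
study conditions for five seeds (the recovery study), plus one smaller
60 × 50 grid configuration for orchestration tests; unit tests use grids
up to 20 × 20 with exhaustive brute-force oracles. These sizes were
chosen so the whole suite completes comfortably on a single CPU while
still exercising every stage at its default settings.

A caveat the recovery study itself surfaces: random-forest partial-effect
curves are flat-topped — near the optimum the response varies by ~0.01
over a ~1.5 °C band — so the *single grid point* at which such a curve
attains its maximum is an unstable estimator of the niche optimum (about
±0.5 °C here), even when the optimum is plainly recovered at the
granularity at which response curves are read in practice. Downstream
users who need a point estimate of an optimum should read it from the
curve's high plateau, not from the argmax alone.

## Known limitations

* No projection support; inputs must share the WGS84 geographic grid.
* Compressed or tiled GeoTIFFs are not read — the codec covers the
  uncompressed single-band strip layout the package itself writes.
* Random holdout splits are optimistic for spatially autocorrelated data;
  spatial-block cross-validation is the known remedy and is out of scope
  here.
* The ensemble is an unweighted mean above a hard AUC gate; AUC-weighted
  averaging is a plausible alternative the package deliberately does not
  default to, because the gate-then-average reading keeps the two roles
  of the AUC (quality control vs weighting) separate.
* MaxEnt, target-group backgrounds and bias files are not implemented.
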