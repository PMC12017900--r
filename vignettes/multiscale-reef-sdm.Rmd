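---
title: "Multiscale reef terrain analysis and presence-background SDMs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale reef terrain analysis and presence-background SDMs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(reefscape)
```

This vignette is the package's own account of its models and the design
choices behind them: what is computed, under which assumptions, which
parameters matter, and what the synthetic-data tests do and do not
establish. It states no empirical result that the test suite does not
itself compute.

## 1. Raster model and I/O

A `reef_grid` is a numeric matrix with a square-pixel affine transform
(origin at the top-left corner) and `NA` as nodata; depths are negative
elevations in metres in a projected CRS. Because no GeoTIFF-capable R
package is available in the target environment, grids are exchanged as
plain-text ESRI ASCII grids (`.asc`) with a JSON sidecar carrying the CRS
identifier and source tag; values are written at full double precision so a
write-read round trip is bit-identical. Reef outlines travel as GeoJSON
polygons; point-in-polygon and point-to-polygon distances are computed
directly (even-odd ray casting; segment projection), which is all the
cropping and buffering steps need.

## 2. DEM preprocessing and the Gaussian pyramid

Raw satellite-derived depth products arrive as positive integers in
centimetres; `preprocess_aca()` divides by a configurable divisor (default
−100) and fills nodata in two stages: a *single* 3×3 valid-neighbour-mean
pass (fills read only original values, so fill order cannot matter),
followed by fallback to an independent co-registered depth grid. A cell
stays nodata only when both sources are empty. Filling is deliberately not
iterated to convergence: a single pass is what the gap statistics of such
products require, and iterative diffusion would invent structure.

`gaussian_reduce()` is one pyramid REDUCE step: separable 5-tap binomial
kernel (1,4,6,4,1)/16, half-sample symmetric (reflect) padding, decimation
keeping even-indexed rows/columns so the parent origin is preserved and the
pixel size doubles. The literature this follows names the pyramid algorithm
but not its kernel; the classic binomial REDUCE is the canonical choice and
the dense-convolution oracle in the test suite pins it to 1e-12. Nodata is
handled by renormalising the kernel over valid cells — the output is a
convex combination of valid inputs, hence never outside their range.
`build_dem_set()` applies this to the 15 m source (4 levels), the 30 m
source (3 levels) and passes the 100 m source through: eight levels.

## 3. Terrain attributes

All slope/aspect/curvature quantities come from one kernel: a least-squares
quadratic surface `z = ax² + by² + cxy + dx + ey + f` over a `fit_window`
neighbourhood (default 3×3), exact for polynomials of degree ≤ 2. Cells
whose window leaves the grid or touches nodata are nodata — the usual focal
edge policy, which also makes the plane invariants exact rather than
approximate. Conventions:

- **SLOPE** `atan(√(zx² + zy²))`, radians in [0, π/2).
- **EAST/NORTH** sine/cosine of the downslope azimuth (north = 0,
  clockwise). Cells flatter than `flat_tol` (1e-6 rad) have no defined
  orientation and get nodata; this keeps the unit-circle identity
  `EAST² + NORTH² = 1` exact wherever defined.
- **VCU** (vertical/profile curvature) is the normal-section curvature in
  the downslope direction with *positive = upwardly concave* (channel
  floors along flow), **HCU** (horizontal/plan curvature) the cross-slope
  curvature with *positive = sideward convex* (ridges). Both are set to 0
  where the gradient vanishes, where the decomposition is undefined.
- **VRM** sums unit surface normals `(−zx, −zy, 1)/√(1+|∇z|²)` over
  `vrm_window` and reports `1 − ‖Σn‖/n_valid`: exactly 0 on any plane,
  approaching 1 for mutually cancelling normals.
- **BPI** subtracts the mean over a Euclidean annulus (default 1 < d ≤ 3
  cells) from the cell's elevation; raw metres, not z-scored (some BPI
  toolboxes standardise; the unit conventions here keep metres).
- **SVF** casts `svf_azimuths` rays (default 16) of `svf_radius` cells
  (default 10), takes the maximal positive obstruction angle per ray and
  reports `1 − mean(sin h)`; rays truncated at the grid edge use the
  available samples.

No published convention fixes the window sizes, annulus radii or ray
radius; the defaults above are the conventional small-window choices for
reef-scale morphometry, and all are config-exposed.
Windows are specified in cells, so one parameter set scales its
neighbourhood extent with each pyramid level — the essence of a multiscale
predictor stack. `derive_all()` emits depth plus the eight attributes per
level: 9 × 8 = 72 layers for the canonical input.

`compare_sources()` samples up to `n_points` cells (seeded; at most one per
coarsest-grid pixel, mirroring scatterplot practice for nested grids),
restricted to cells valid in both stacks, and reports Spearman's rank
correlation per shared (resolution, variable) with an `|r_s| ≥ 0.8` flag.

## 4. Vertical accuracy

`correct_to_lat()` linearly interpolates the station tide series in time
and computes `lat_depth = −(raw_depth + tide_height)`. One subtlety is
worth stating plainly: with this additive sign convention, the tide series
entries act as the *correction term added to the observed depth*, so the
synthetic generator writes its depth records as
`raw_depth = cell_depth − tide(t) + noise` — the pair is self-consistent,
and with zero tide and zero noise the loop closes exactly (median Δh = 0,
NMAD = 0 against the sampled DEM; tested). Records whose timestamps fall
outside the tide series span are excluded, not extrapolated.

`vertical_error()` is `Δh = in situ − DEM` at the containing cell, so a DEM
shallower than the diver's measurement gives negative Δh; the orientation
is fixed by that reading and tested. `summarize_error()` reports median and
SD of Δh (SD of the signed errors, not of their magnitudes), `RMSE = √(mean Δh²)`,
`NMAD = 1.4826 · median(|Δh − median Δh|)`, outliers by `|Δh| > 3·RMSE`,
and Q-Q pairs of the sorted sample against normal quantiles with the
sample's mean/SD at plotting positions `(k − 0.5)/n`. No LAT↔MSL datum
adjustment is applied — the field depths are LAT-referenced while the DEMs
are MSL surfaces, and quantifying (not removing) that mismatch is the
point of the module.

## 5. Occurrence preparation

Thinning keeps exactly one presence per occupied pixel of the 15 m
reference grid (first record in a stable sort by id — deterministic) and is
idempotent. Multiple presences per *coarser* pixel are deliberately
accepted. Background sampling draws `n` cells (default 10,000) with
replacement from the union of valid reef cells with probability
`∝ ε·max(d) + d`, where `d` is a Gaussian kernel density (default bandwidth
500 m) of every georeferenced survey coordinate and `ε = 0.05` a floor that
keeps unsampled areas reachable. Several bias mechanisms are in use in the
SDM literature; the kernel-with-floor form is this package's declared
choice, with `bandwidth → ∞` reducing to uniform sampling
(tested by χ²).

## 6. The MaxEnt-style engine

Feature classes follow the untransformed MaxEnt families: linear (min-max
scaled raw columns), quadratic (squares of scaled values) and pairwise
products, combined as L / LQ / LP / LQP. Scaling ranges are learned on the
training table and stored in the model, which is what makes predictions
invariant (to 1e-10) under affine rescaling of raw inputs.

Fitting uses the infinitely-weighted logistic-regression equivalence, as in
the reference implementation: an L1-penalized logistic regression of
presence (1) against background (0) with background rows weighted 100:1,
solved by coordinate descent (glmnet) along a decreasing penalty path whose
endpoint makes the effective per-feature penalty `rm · c(class, m) · sd_j /
√m` on the weighted likelihood — `m` the presence count and `c` the
published default schedule per feature class, piecewise-linearly
interpolated over `m` (linear: 1.0/0.2/0.05 at m = 10/30/100; quadratic:
1.3/0.8/0.5/0.25/0.05 at 0/10/17/30/100; product:
2.6/1.6/0.9/0.55/0.05). Hinge and threshold features are omitted: this
workflow uses only L/Q/P classes. Zero-variance features are
always excluded. Because the presence-background intercept is not
identifiable under the weighting, it is recalibrated after fitting by
unweighted maximum likelihood with the penalized slopes as offset (damped
Newton on a concave 1-D objective); this leaves all rankings untouched,
makes an all-zero model predict the observed prevalence, and gives the BIC
its textbook closed form on degenerate fixtures. The map/vector output
transform is logistic (the cloglog alternative is not used; recorded in
model metadata).

Two degenerate regimes deserve mention: on linearly separable data with a
near-zero penalty there is no finite optimum — the solver warns and
returns the last converged solution on the path (ranking is still perfect);
at very large multipliers all penalized coefficients are exactly zero.

## 7. Evaluation

- **AUC** is the Mann-Whitney pair statistic via midranks — identical to
  exhaustive pair counting with ties at ½ (tested exactly).
- **BIC** is `k·ln(n) − 2·lnL̂` with `k` = nonzero coefficients + 1 and
  `lnL̂` the *unpenalized*, unweighted binomial log-likelihood at the
  fitted coefficients (the lasso-df convention); probabilities are clipped
  to `[1e-12, 1 − 1e-12]`.
- **Leave-one-reef-out CV**: per iteration and held-out reef, training data
  are all other reefs' presences plus a random 75% of background, test data
  the held-out reef's presences plus the other 25%; the background split is
  drawn in triplicate per fold, so R reefs × I iterations × 3 records per
  candidate. BIC is computed on the training rows, AUC on the test rows.
- **Jackknife**: per variable, only-`v` / without-`v` / full-model AUCs on
  seeded 75/25 holdouts (split within class), *averaged over 3 re-splits* —
  a deliberate deviation from the single-holdout design note, trading three
  extra small fits for a visibly lower-variance estimate; `AUC_ONLY > 0.7`
  flags "top" variables (the "acceptable discrimination" rule).
- **Model grouping**: Kruskal-Wallis on midranks, Dunn's pairwise z tests
  with the tie-corrected variance, Holm adjustment, and a greedy
  insert-absorb compact letter display (groups sharing a letter are
  statistically indistinguishable at α = 0.05).
- **Habitat overlap**: probability maps are binned into (0,25], (25,50],
  (50,75], (75,100] percent (0 assigned to the first bin) and the fraction
  of suitably-classed cells is reported per bin with mean ± SE across
  reefs.

## 8. The synthetic reef world

The generator exists so that every module is exercised end-to-end with a
known answer. Its truth surface is analytic: per reef a radial profile —
lagoon basin (default 12 m), shoaling flat, crest ring (1 m), an upper
slope descending to 10 m, a steep fore-reef wall, then a surrounding plain
at 25 m — combined across reefs by taking the shallowest surface, plus a
seeded Gaussian random-field roughness (spectral synthesis; default SD
0.8 m, correlation length 60 m, the scale of spur-and-groove and bommie
relief visible at 15 m pixels). The upper-slope width varies around each
reef through an exposure factor (windward margins drop almost directly off
the crest; leeward margins carry a wide gentle terrace) — the classic
asymmetry of platform reefs. Two defaults encode field constraints rather
than convenience: the lagoon is *deeper* than the 8 m colony depth cap, so
crests and upper slopes form the sampled band exactly as shallow-water
colony surveys describe; and the three "sources" sample the same truth at
15/30/100 m cell centres with independent sensor noise (0.3 m SD).

Occurrences follow a logistic response on *rank-(ECDF-)scaled* predictor
layers (scaled to [−1, 1] over candidate cells). Rank scaling, rather than
z-scoring, is the robustness choice: terrain attributes are heavy-tailed
(a few wall cells carry extreme slopes), and a rank scale keeps every named
variable's contribution comparable without letting outliers set the scale.
Candidate cells are those shallower than `depth_cap_m` (8 m) inside a reef
outline; `n_presence` cells are drawn without replacement weighted by the
response probability; coordinates get 3 m GPS jitter and depth records get
1 m dive-computer noise — the stated accuracies of handheld-GPS tows and
dive computers. Tides are single semidiurnal sinusoids per station
(amplitude 0.8 m, period 12.42 h, seeded phase): sufficient to exercise
interpolation, not oceanographically realistic.

**The strong-signal recovery fixture** used by the acceptance suite
generates presences from 30 m slope and 15 m BPI (coefficients 5 each, on
the rank scale), with depth available to the model as in the field
protocol and three smooth pure-noise layers as negative controls, at
144×144 cells / 3 reefs / 250 presences / 800 background — scaled down
from the 256-cell default purely to fit the stated runtime budget. The
30 m choice for slope is not incidental: fine-scale slope at 15 m is
dominated by sensor-noise gradients, and slope genuinely carries its
information at the coarser levels. What a green run establishes: under a
known strong terrain response with realistic observation noise, the full
pipeline (derive → thin → biased background → LQ2 fit → jackknife /
leave-one-reef-out) marks the generating variables as top and the noise
variables as not-top, and transfers across reefs with held-out AUC > 0.8.
What it does not establish: anything about real species, real bathymetry
accuracy, detection processes, or spatial autocorrelation beyond the
thinning rule — the generator has none of the biological or oceanographic
structure that makes real SDMs hard.

## 9. Numerical choices and degenerate inputs

Convergence: glmnet threshold 1e-9 with a 50-point path; intercept
recalibration iterates damped Newton to 1e-12. Ties: midranks everywhere
(AUC, Spearman, Kruskal-Wallis/Dunn); selection ties broken by higher mean
AUC, then lower RM, then simpler feature class (L < LQ < LP < LQP).
Empty annuli, all-nodata windows and off-grid points yield nodata (never
silent zeros); rows with any missing predictor are dropped and counted.
Q-Q plotting positions are `(k − 0.5)/n`. The YAML config maps the bare
key `n` (parsed as boolean by YAML 1.1) back to its intended name.

## 10. Known limitations

- ESRI ASCII I/O carries no full CRS definition — only an identifier in
  the sidecar; reprojection is out of scope and inputs must be
  pre-aligned.
- The bias kernel is declared, not shown equivalent to the target-group
  background mechanism of the reference protocol.
- BIC on a penalized fit uses the nonzero-coefficient df convention; other
  df estimators would shift BIC by a model-size-dependent amount.
- The jackknife uses holdout splits, not the full leave-one-reef-out
  machinery, for tractability.
- Bit-level agreement with the reference MaxEnt/maxnet binaries is not
  claimed anywhere; the equivalence is structural (same feature classes,
  penalty schedule and weighting scheme).
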