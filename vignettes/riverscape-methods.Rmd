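---
title: "Methods: from elevation model to habitat overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from elevation model to habitat overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms, parameter choices and
numerical conventions behind `riverscape`, and states plainly where a design
was genuinely open and what we decided.

## 1. Hydrological extraction

**Depression filling.** Closed sinks in a DEM stop flow routing, so every
cell is raised to its pour-point elevation with a boundary-seeded
priority-flood sweep (min-heap over elevation, insertion order breaking
ties for platform determinism). The fill is *epsilon-free*: filled areas
become exactly flat rather than being given an artificial micro-gradient,
and flats are resolved later. Cells outside depressions are untouched. An
all-nodata grid is an error ("empty terrain").

**D8 flow directions.** Each valid cell drains to the neighbour with the
steepest drop per unit distance; diagonal distance is cell size × √2. Among
equal steepest drops the first neighbour in clockwise order starting at East
wins — an arbitrary but fixed rule, chosen so results are identical across
platforms. Flat cells (which exist exactly where filling flattened a sink)
are resolved by a breadth-first sweep from their spill cells: each flat cell
points at the equal-elevation neighbour through which it was first reached,
so all flat flow converges on the flat's outlet and the graph stays acyclic.
Edge cells (and cells beside nodata) with no downslope neighbour are
outlets that drain off-grid — the open-boundary convention of standard
watershed tools. A flat region with no outlet after resolution is an error
naming a cell in the region.

**Flow accumulation** counts the cells draining through each cell,
*including itself*, in one topological (Kahn) sweep; a cycle is an error.
The self-inclusive convention makes the headwater rule directly testable:
a cell is a stream cell iff `count × cellSize² ≥ threshold`. The default
threshold is 2.0 km², the conventional catchment area at which a headwater
channel is assumed to begin; it is a tunable parameter, not a constant.

**Vectorization and reach splitting.** Stream cells are traced cell-centre
to cell-centre into confluence-to-confluence segments, then each segment is
subdivided from its upstream end into reaches of the chosen grain (default
1.0 km — an intermediate scale at which stream fish complete important parts
of their life histories). Numerical conventions:

- Split points fall at exact distances along the polyline, so split
  vertices are interpolated between cell centres; all original vertices
  remain at cell centres, and total length is conserved exactly.
- A terminal remainder ≥ 1% of the grain becomes its own reach; smaller
  remainders merge into the previous reach. This preserves confluence nodes
  exactly and avoids zero-length slivers. A 3.4 km segment at 1.0 km grain
  therefore yields reaches of 1.0, 1.0, 1.0 and 0.4 km.
- A reach's "downstream cell" (the seed of its catchment queries) is the
  traced cell nearest its downstream endpoint.

**Strahler order** is assigned topologically: sources are order 1; where
streams meet, the downstream order is the maximum inflowing order, +1 when
two or more inflows share that maximum; between confluences the order is
inherited.

## 2. Reach attributes

Reach gradient is `100 × (upstream − downstream elevation) / path length`,
with apparent uphill flow (elevation noise at reach scale) clamped to 0
under a warning. Sinuosity is path length over endpoint chord; coincident
endpoints are an error. Confluence density, stream density, catchment area
and all environmental summaries are computed over the reach's *upstream
catchment* — the only support area the workflow defines per reach. Stream
length inside a catchment counts the reaches whose downstream cell lies in
the catchment (catchments are upstream-closed, so this includes whole
reaches). The slope grid uses Horn's 3×3 kernel on the filled DEM, reported
in degrees × 100, with edge replication at borders.

The collinearity filter walks candidate predictors in a priority order —
hydroclimate, then topography, then landcover, then soil, classified by
name, and within a class in table order — keeping a variable only when its
|Pearson r| with every kept variable stays below 0.7. The greedy pass with a
declared priority makes the selection deterministic and reproducible;
constant columns are dropped (with a warning) before any correlation is
computed.

## 3. The maximum-entropy model

Predictors are min–max normalized with bounds learned from the *background*
and clamped to [0, 1] on transfer (the reference MaxEnt convention). Feature
classes: linear, quadratic, pairwise products, forward and reverse hinges at
50 evenly spaced knots (default), and step thresholds. With automatic class
selection, fewer than 10 presences use linear only; 10–14 add quadratic;
15–79 add hinge; 80+ add product.

The fitter maximizes the penalized presence log-likelihood of the Gibbs
distribution over the background (see the README for the formula). The
per-feature L1 weight is `classBeta(n) × sd(feature at presences) / √n`,
with the class betas interpolated from the published MaxEnt tables
(linear/quadratic/product: 1.0 at ≤10 presences to 0.05 at ≥100; hinge 0.5;
threshold 2.0 to 1.0), the presence-sample sd floored at 0.001 on the [0,1]
feature scale, and the regularization multiplier m scaling everything.

Optimization runs in two phases: FISTA (proximal gradient with backtracking
and adaptive momentum restart) to locate the active set cheaply, then a
damped active-set Newton loop with KKT screening, which drives the solution
to high precision even when correlated features (a variable and its square,
overlapping hinges) leave the likelihood nearly flat. The fit is accepted
when every Karush–Kuhn–Tucker residual is ≤ 1e-9 × n (with a fallback
acceptance at 1e-4 × n after a stall); otherwise fitting errors out rather
than returning a dubious model. Identical inputs give identical fits — no
randomness enters the optimizer.

Predictions: raw values `exp(βᵀf − log Z)` sum to 1 over the training
background; the default cloglog output is `1 − exp(−e^H raw)` with H the
entropy of the fitted background distribution; a logistic variant is
available behind a flag. Both transforms are strictly increasing in raw, so
rankings never depend on the choice.

**Occurrence handling.** Records with positional uncertainty over 100 m are
discarded, as are off-grid records; duplicates within a grid cell collapse
to one. Background reaches are sampled uniformly inside a buffer around the
occurrences. The buffer radius is deliberately a *required* parameter in
study code (the synthetic pipeline uses 15–40 km): the right radius depends
on the species' accessible area and no universal default is defensible.
When the buffered pool holds fewer reaches than the requested background
size (10,000 by default), sampling falls back to with-replacement draws —
duplicated background reaches simply act as weights in the Gibbs
normalization.

## 4. Evaluation and selection

Candidates are all combinations of the configured regularization
multipliers and feature-class strings. Each candidate is fitted on all
presences (AICc, parameter count = non-zero coefficients, final predictor)
and k-fold cross-validated (default 10 folds) so every presence is scored
by a model not trained on it. Partial ROC compares the pooled held-out
presence scores against fold-averaged background scores (averaging on the
cloglog scale): per bootstrap replicate, half the test presences are
resampled with replacement and the area under the sensitivity versus
proportion-predicted-present curve above sensitivity 1−E is divided by the
same area under the random diagonal; the p-value is the share of replicates
with ratio ≤ 1. Defaults E = 0.05, 500 iterations, 50% resampling, α = 0.05
follow the conventions of the partial-ROC literature. The curve is a step
function over the unique score thresholds, integrated by trapezoid — exact
for tie-free staircases. Degenerate inputs (all scores identical) pin the
ratio at 1 under a warning. With small test sets the ratio is structurally
slightly above 1 under the null (the restricted region conditions on
sensitivity ≥ 1−E), which is why the package's own null checks use a few
hundred test scores and judge the ratio against its bootstrap spread.

The omission rate at E compares held-out scores with the E-quantile
(`ceiling(E·n)`-th smallest) of the full-model training scores. Selection
filters candidates to partial-ROC p < α, then omission ≤ E, then minimizes
AICc (`−2LL + 2k + 2k(k+1)/(n−k−1)`, +∞ when n ≤ k+1), breaking ties by
fewer parameters and lower multiplier. If the omission filter empties the
set, the significant candidate with minimal omission is returned and
flagged — a fallback, not a silent relaxation.

## 5. Thresholds and overlap

MTP binarizes at the minimum training-presence suitability (zero training
omission by construction — appropriate for well-curated records); P10 at
the `ceiling(0.1 n)`-th smallest training score (tolerating up to 10% of
dubious records — appropriate for mixed-provenance data). Ties at the
threshold count as suitable, which is what guarantees the MTP property, and
implies P10's suitable set is always nested within MTP's. Overlap is
reported on both scales the field uses: percent of *native*-suitable
reaches also suitable for the invader (asymmetric by design) and shared
kilometres (symmetric), plus an any-invader union variant. Elevation
comparisons use the reach midpoint DEM value; Kruskal–Wallis across ≥3
groups and Wilcoxon rank-sum for pairs are the only statistics delegated to
standard library routines, and the Kruskal–Wallis formula is independently
hand-checked in the test suite.

## 6. What the synthetic landscape does and does not emulate

The generators produce: drainable terrain (tilted planes, V-valleys, and
dendritic surfaces built from multi-scale Gaussian-smoothed noise over a
regional tilt), smooth environmental rasters (temperature follows a
−6.5 °C/km lapse with a mild anomaly field, precipitation and landcover are
smooth fields in plausible units), and virtual species with known logistic
linear-quadratic suitability over standardized reach attributes, sampled
without replacement with probability proportional to suitability, with
positional uncertainties kept below the 100 m cleaning cutoff.

Defaults are chosen so the study is well posed: 256×256 cells at 100 m,
0.5 km grain (several hundred reaches), 80 presences per species (~15% of
reaches — sparse, as real occurrence sets are relative to basin size), and
species with pronounced niches (a cold-water native with a quadratic
temperature response, an invader preferring milder, wetter reaches at
moderate prevalence). A virtual species with a near-flat response is
statistically indistinguishable from background, and the selection stage
will correctly refuse to endorse any model for it.

What passing tests therefore show: the kernels match brute-force oracles;
the fitter matches a generic convex optimizer; known suitability surfaces
are recovered (Spearman ≥ 0.9 at 200 presences / 10,000 background with
linear-quadratic features); the evaluation statistics behave correctly
under null and strong-signal regimes. What they do not show: realism of
Himalayan topography, spatial sampling bias, occurrence errors beyond
positional uncertainty, cross-basin transfer under novel climates, or
braided/lake-influenced hydrography (D8 cannot represent those; see
limitations).

## 7. Problem sizes and tolerances used in the checks

The test suite runs hydrology oracles on ≤20×20 seeded grids (exact
equality), length conservation at 1e-6 relative, fitter–oracle agreement at
1e-4 coefficients, raw normalization at 1e-8, entropy consistency at 1e-6,
partial-ROC brute-force agreement at 1e-6, recovery on five seeded 256×256
landscapes, null calibration of partial ROC over 200 runs with 200 test
scores each, and a full two-species pipeline on a 256×256 landscape run
twice to confirm bit-identical outputs. These sizes are the package's
choices for fast, decisive checks; all generators scale to larger grids.

## 8. Known limitations

- Single-direction D8 routing: no braided channels, distributaries, lakes
  or D-infinity dispersion.
- Projected, square-cell rasters only; geographic (degree) grids are out of
  scope, as is raster resampling (mismatched rasters are an error).
- The reach "downstream cell" is the nearest traced cell to the split
  point, so catchments of mid-segment reaches are quantized to cell
  resolution.
- MTP is sensitive to a single marginal training record by construction;
  that is its definition, not a bug — use P10 for mixed-provenance data.
- Background-with-replacement (when the buffered pool is small) reweights
  rather than enlarges the environmental sample; very small pools still
  yield weak models, and the selection stage will say so.
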