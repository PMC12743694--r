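---
title: "Quantifying forest connectivity loss and prioritising reforestation offsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying forest connectivity loss and prioritising reforestation offsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestconn)
```

## The problem

Land-consuming projects — the motivating case is a reservoir-based
hydropower scheme — remove and fragment forest habitat. Environmental
impact assessments rarely quantify the loss of *connectivity*: the degree
to which the remaining forest still lets terrestrial wildlife move through
the landscape. `forestconn` implements a two-part framework:

1. **Impact**: model structural forest connectivity with circuit theory
   before and after construction, over an ensemble of resistance surfaces,
   and map the percent change in current density.
2. **Offset**: find deforested areas whose reforestation would best restore
   connectivity, ranking 10-ha hexagonal candidate cells by the variation
   of the Integral Index of Connectivity (varIIC) at several dispersal
   distances, landscape-wide and within riparian zones.

The approach is *structural*: it uses only the physical arrangement of
land cover, not species-specific movement data. That keeps data
requirements minimal — one land-cover raster per date, an elevation model,
the project footprint and the river network — at the cost of ecological
nuance (no demography, no behaviour, no barrier semantics beyond
resistance values).

## Scenario preparation

Land cover is reduced to five classes — forest, grassland, cropland,
waterbodies, unsuitable — via `reclassify()`; the default table groups
wooded land with forest, riverbeds with water bodies, and glacier, snow,
built-up and bare classes as unsuitable. Rasters may be coarsened with
`resample_nearest()` (nearest cell centre; equidistant ties resolve to the
smaller row then column index, so results are deterministic).

Two conventions matter and are fixed deliberately:

* **Tree line.** `apply_elevation_mask()` marks cells *strictly above*
  3600 m as unsuitable; a cell at exactly 3600 m keeps its class. The
  threshold is the upper tree line of the Himalayan mid-hills setting and
  is a plain argument for other regions.
* **Footprint burning.** `burn_footprint()` converts cells whose *centre*
  lies inside the footprint polygon. Centre containment is unambiguous at
  any resolution and makes the operation idempotent.

`detect_deforestation()` compares two dates per cell: forest at both
dates is `stable_forest`; forest converted to cropland or unsuitable is
`deforested`; every other transition — including forest to grassland or
waterbodies — is `other`, because those conversions are not reforestation
opportunities in the same sense.

## The resistance ensemble

Rather than committing to one species' cost surface, the analysis sweeps
a factorial ensemble: forest is always 1 (best habitat), unsuitable always
100 (effective barrier), and cropland, grassland and waterbodies each take
low (10), medium (50) or high (90) resistance. The default 3^3 = 27
profiles (`enumerate_profiles()`) emulate ecologically distinct movement
guilds; the level sets are configurable for users who want a finer or
species-informed sweep. Resistances are dimensionless multipliers of
per-cell traversal cost.

## Circuit model

`build_network()` turns a resistance raster into an undirected conductance
network on the 8-neighbour lattice. Orthogonal neighbours get conductance
$1 / ((r_i + r_j)/2)$ — the average-resistance scheme that raster circuit
tools default to — and diagonal neighbours get that value divided by
$\sqrt{2}$, reflecting the longer traversal.

`cumulative_current()` solves, for every unordered pair of focal nodes,
the Laplacian system $L v = b$ with unit current injected at one node and
extracted at the other (ground voltage 0). The implementation factorises
the reduced Laplacian once per network component (sparse Cholesky) and
reuses the factor across all pair right-hand sides; solutions are exact to
machine precision, and the suite checks them against a dense
pseudoinverse oracle at $10^{-8}$. Per-cell current density is the half
sum of absolute currents on the cell's incident edges; the two focal cells
carry the injected current, 1. Focal pairs that fall in different network
components are skipped with a warning rather than aborting the run.

Focal nodes are placed uniformly at random (seeded) in a buffer ring
around the study area (`sample_focal_nodes()`), which keeps the
artificially high current densities near injection points outside the
area of interest. The ring width defaults to 20 % of the maximum extent
length and can be fixed in metres instead; focal nodes may fall on any
land-cover class, since the placement is meant to be agnostic about where
animals enter the landscape.

## Consensus and change

With 27 profiles, many current maps are near-duplicates.
`spearman_dedup()` retains one representative per duplicate cluster:
a greedy keep-first scan in profile order drops any map whose Spearman
rho with an already-retained map exceeds 0.99. We read the deduplication
this way (rather than discarding *all* correlated maps) because the
alternative can retain nothing. The retained maps are summed
(`sum_consensus()`); a mean would differ only by a constant factor, and
the downstream percent change is invariant to that choice whenever both
scenarios retain equally many maps.

`percent_change()` maps $100 (\mathrm{after} - \mathrm{before}) /
\mathrm{before}$ per cell, signed and unclamped. Cells with zero current
in both scenarios are 0; cells where current appears from nothing are
masked undefined rather than infinite.

## Offset prioritisation

The study area is tessellated into 10-ha pointy-top hexagons anchored at
the extent's lower-left (`build_hexgrid()`; edge length
$s = \sqrt{2A/(3\sqrt3)} \approx 196.2$ m for $A = 10$ ha). A hexagon is
*forested* when all of its pixels are stable forest — applied as a
fraction of at least 0.999 to absorb rasterisation edge effects — and
otherwise *deforested* when at least 10 % of its pixels are deforested.
Adjacent forested hexagons merge into habitat patches
(`merge_forest_patches()`); deforested cells never merge, since each is a
separate reforestation decision.

Candidates are deforested hexagons whose mean after-construction current
density lies strictly above the 20th percentile (type-7
linear-interpolation quantile) of the deforested population
(`percentile_filter()`). The percentile population is the deforested
cells' currents, not the whole map: the filter chooses among
reforestation options, so the reference distribution is the options
themselves.

The Integral Index of Connectivity over the patch set is

$$\mathrm{IIC} = \frac{\sum_i \sum_j a_i a_j / (1 + nl_{ij})}{A_L^2}$$

with $a_i$ the patch attribute, $nl_{ij}$ the minimum number of links
between patches $i$ and $j$ on the binary graph (linked iff edge-to-edge
distance $\le d$), and $A_L$ the analysis-extent area. The patch
attribute is the summed after-construction current over the patch's
pixels divided by patch area — i.e. its mean current density. The source
phrase "current density divided by patch area" is ambiguous between
summed and averaged current; we use summed-over-area because it weights a
patch by the total flow it carries while remaining size-normalised, and
the two readings differ per patch only by a constant factor when patch
sizes are equal.

Each candidate is evaluated one at a time as a "node to add": links and
link counts are recomputed with the candidate present, and
$\mathrm{varIIC} = 100 (\mathrm{IIC_{with}} - \mathrm{IIC_{base}}) /
\mathrm{IIC_{base}} \ge 0$. Scoring runs at 500 m, 1 km and 2 km to
represent species with different dispersal abilities; rankings are
independent per distance (a cell may be selected at several distances —
the overlap categories report exactly that). The selection size is
$N = \mathrm{round}(\text{lost forest area} / \text{cell area})$, ties
broken by ascending candidate id. The riparian variant ranks the subset
of candidates intersecting any river polyline, with the same scores and
the same $N$.

`export_conefor()` writes plain-text node and pairwise-distance files so
the varIIC computations can be verified with external connectivity
software.

## The synthetic landscape

The package ships no real rasters; `generate_landscape()` produces seeded
synthetic inputs with the structure the analysis assumes. Defaults mirror
the motivating setting: 60 m cells, 60 % forest (thresholded smoothed
Gaussian noise; the `fragmentation` parameter is the smoothing length in
cells, so southern-style fragmented mosaics are one knob away), a
non-forest matrix that is mostly cropland with some grassland and a
little built-up land, a meandering north-south river rasterised to
waterbodies, an elevation gradient rising northwards across the 3600 m
tree line, a reservoir-shaped footprint straddling the river (about
0.6 % of the extent, the footprint-to-study-area ratio of the motivating
project), and clustered deforestation converting 4 % of date-1 forest to
cropland (80 %) or unsuitable (20 %) — the approximate two-decade loss
rate in the motivating landscape. Identical configuration and seed give
bit-identical output.

What the generator does *not* emulate: terrain-driven hydrology, climate
layers, road networks, species occurrence, or the spatial
autocorrelation structure of real census-derived land-cover error. Tests
passing on synthetic landscapes therefore demonstrate the correctness of
the algorithms and the qualitative behaviour of the framework (corridor
loss, landscape-scale decline, corridor-first offsets), not calibrated
predictions for any real landscape.

`pinch_fixture()` is the sharpest diagnostic: two forest blocks joined by
a single 3-cell corridor through an unsuitable band, with an
after-scenario burning the corridor. Because the burned corridor becomes
unsuitable — resistive, not absent — the after-current spreads across the
whole band instead of vanishing, so per-cell declines in the corridor
approach but do not reach −100 %; the suite requires every corridor cell
below −70 % and a mean below −85 %, which the fixture comfortably meets
(observed means around −93 %).

## Numerical choices

* Sparse Cholesky on the reduced Laplacian; one factorization per
  component per surface, reused across pairs. Residuals are at machine
  precision (the suite asserts $10^{-8}$ against an independent dense
  oracle).
* Profiles that assign identical resistances to every class *present* in
  a raster produce identical surfaces; the pipeline solves each distinct
  surface once and attributes the map to every member profile. This is a
  pure computation-sharing step — the ensemble semantics (27 maps into
  the deduplication) are unchanged.
* Spearman rho uses average ranks for ties; two constant maps count as
  duplicates (rho 1), a constant against a varying map as unrelated.
* Nearest-neighbour ties, hexagon anchoring, pair ordering and focal
  sampling are all deterministic given the seed; `profile_id` is 1-based.
* Percentiles are R's default type-7 linear interpolation.
* Geometry (point-in-polygon, segment and polygon distances, polyline
  intersection) is implemented in plain planar arithmetic on the shared
  projected CRS; the package refuses to combine rasters whose CRS labels
  or grids differ, and never reprojects.

## Problem sizes

The shipped tests and the acceptance script use deliberately small
instances — landscapes of tens of cells to 100 × 100, ensembles of 27,
up to 12 focal nodes, random patch sets of up to 50 — chosen so that the
full factorial pipeline still exercises every code path while a complete
run takes seconds. The same functions scale to study-area-sized rasters;
the dominant cost is one sparse factorization per distinct resistance
surface plus one triangular solve per focal pair.

## Known limitations

* Structural connectivity only; resistance values are ordinal expert
  levels, not fitted movement costs.
* Pairwise mode only — no all-to-one or omnidirectional variants.
* Patch geometry is the union of member hexagons kept as a cell set;
  distances are exact boundary-to-boundary minima over member cells, but
  no dissolved polygon is produced.
* Candidates are scored one at a time; the ranking is not a joint
  (portfolio) optimisation, so complementarity between candidates is not
  captured.
* Reprojection, cloud masking and more than two land-cover dates are out
  of scope.

## A minimal run

```{r example, eval = FALSE}
L <- generate_landscape(landscape_config(width = 60, height = 60, seed = 1))
cfg <- run_config(n_focal = 8, seed = 1)
imp <- run_impact(L, cfg)
summary(imp$change$values[!is.na(imp$change$values)])
off <- run_offset(L, imp, cfg)
off$ranking
```
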