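# forestconn

Quantify the forest-habitat connectivity loss caused by a land-consuming
project and prioritise reforestation offsets that restore it.

`forestconn` is aimed at impact-assessment practitioners and landscape
ecologists who need a quantitative connectivity component for an EIA: it
compares before- and after-construction scenarios with circuit-theory
connectivity modelling over an ensemble of resistance surfaces, and then
ranks candidate reforestation sites by how much each would improve
connectivity for species with different dispersal abilities.

## What it computes

**Impact.** Land cover (five classes: forest, grassland, cropland,
waterbodies, unsuitable) becomes a conductance network on the 8-neighbour
lattice: orthogonal neighbours get conductance `1/((r_i + r_j)/2)`,
diagonals that value divided by √2. For each of 27 factorial resistance
profiles (forest = 1, unsuitable = 100; cropland, grassland, waterbodies
∈ {10, 50, 90}) the package solves unit current flow between every pair of
randomly placed focal nodes — exact sparse Cholesky solves of the graph
Laplacian, one factorization per surface reused across pairs — and
accumulates per-cell current density. Near-duplicate maps (Spearman
ρ > 0.99) are dropped, the rest are summed into a consensus map per
scenario, and the change map is `100·(after − before)/before` per cell.

**Offset.** Deforestation between two land-cover dates (forest →
cropland/unsuitable) is detected per cell, the study area is tessellated
into 10-ha hexagons, and deforested hexagons above the 20th percentile of
after-construction current density become candidates. Forested hexagons
merge into habitat patches with attribute `a_i` = mean current density,
and each candidate is scored by the variation of the Integral Index of
Connectivity when added as a new node:

    IIC = [ Σ_i Σ_j a_i a_j / (1 + nl_ij) ] / A_L²
    varIIC = 100 · (IIC_with − IIC_base) / IIC_base

with `nl_ij` the minimum number of links between patches on the binary
graph (linked iff edge-to-edge distance ≤ d) and `A_L` the analysis-extent
area. Scoring runs at 500 m, 1 km and 2 km dispersal thresholds; the
selection size per distance matches the forest area lost to the project,
and a riparian variant ranks the candidates intersecting the river
network.

A seeded synthetic-landscape generator (`generate_landscape()`,
`pinch_fixture()`) supplies reproducible inputs, since the framework's
real inputs are national land-cover products that cannot be
redistributed.

## Worked example

```r
library(forestconn)

L   <- generate_landscape(landscape_config(width = 120, height = 120, seed = 1))
cfg <- run_config(n_focal = 8, seed = 1)

imp <- run_impact(L, cfg)
round(summary(imp$change$values[!is.na(imp$change$values)]), 2)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  -96.63    0.05    0.30   -0.08    0.67   55.11

off <- run_offset(L, imp, cfg)
off$ranking
#> <priority_ranking> N = 1 per distance
#>   d = 500 m: 1 selected, varIIC 22.24 .. 22.24
#>   d = 1000 m: 1 selected, varIIC 24.99 .. 24.99
#>   d = 2000 m: 1 selected, varIIC 30.01 .. 30.01
#>   overlap: 1-distance 0%, 2-distance 0%, 3-distance 100%
```

Reading the numbers: burning the project footprint erases up to 96.6 % of
the current density inside and near the footprint while most of the
landscape is barely touched (median +0.3 % reflects flow rerouting); the
project removes 0.11 km² of forest, so one 10-ha hexagon is selected per
dispersal distance, and here the same candidate wins at all three
distances — reforesting it would raise the IIC by 22–30 % depending on
the dispersal ability assumed. On the `pinch_fixture()` scenario — two
forest blocks joined by a single corridor that the project severs — the
corridor cells lose ~93 % of their current and the top-ranked candidates
at every distance sit in the severed corridor.

The methods vignette (`vignettes/connectivity-offsets.Rmd`) documents the
model, the parameter conventions and the design decisions.

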