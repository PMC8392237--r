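---
title: "Constructing ecological security patterns with ecoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing ecological security patterns with ecoscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoscape)
```

## The problem

An ecological security pattern (ESP) is a spatial network of ecological
*sources* — patches that supply ecosystem services or are ecologically
sensitive — linked by *corridors* through which organisms, material and
energy can move. Building one on a raster landscape takes five modelling
stages: score the land for services and sensitivity, select source patches,
turn the landscape into a movement-resistance surface, trace corridors, and
diagnose where the network is fragile (pinch points) or cheaply improvable
(barriers). `ecoscape` implements the whole chain with plain R objects
(`raster_grid` is a matrix plus cell size and origin) so every stage can be
unit-tested against analytic oracles.

## Ecosystem services

**Habitat quality** follows the classic threat-degradation model. Each threat
(built-up land, cropland, roads by class) has a weight $w_r$, a maximum
effective distance $d_{max}$ and a decay shape. The impact at distance $d$ is
$1 - d/d_{max}$ (linear) or $\exp(-(2.99/d_{max})\,d)$ (exponential, ~0.05 at
$d_{max}$); both are cut to zero beyond $d_{max}$, since a *maximum effective
distance* means exactly that. The per-cell degradation is the
weight-normalized average of (impact × sensitivity of the cell's land class),
and quality is $Q = H_j\,(1 - D^z/(D^z + k^z))$ with $z = 2.5$ and
half-saturation $k$.

Two choices here were genuinely open:

* *Printed decay form.* The exponential impact is sometimes written with
  $d_{max}$ and $d$ transposed in the exponent, a form that grows with
  distance and diverges at $d = 0$; we implement the standard decreasing form
  $\exp(-(2.99/d_{max})\,d)$.
* *Aggregation over threat sources.* The fully general model double-sums over
  every source cell of every threat. Because the weight normalization makes
  degradation a weighted *average* of threat levels, we use the impact of the
  *nearest* source per threat — scale-free, reproducible, and independent of
  how finely a source area is rasterized. `degradation(method = "sum")`
  provides the all-source accumulation (clipped to 1 per threat) for small
  rasters.
* $k$ defaults to 0.5 (quality halves at mid-scale degradation); it is the
  one half-saturation parameter the user should revisit when typical
  degradation shifts.

**Water yield** is the per-pixel annual balance $Y = P - AET$ (mm/yr). AET is
an input raster: no Budyko-type machinery is implemented, because the balance
itself is the model being composed downstream and any AET estimator can feed
it.

**Carbon storage** is a per-class lookup of the four-pool sum (above-ground,
below-ground, soil, dead organic matter, t/ha).

The three layers are min-max normalized and averaged with equal weights.
Min-max normalization of a *constant* raster is defined as all zeros (with a
warning) rather than NaN, so degenerate layers keep downstream sums defined.

## Ecological sensitivity

Habitat sensitivity overlays four sub-scores on the {7, 5, 3, 1} scale
(7 = most sensitive): distance to major roads (breaks at 1, 2, 3 km),
distance to reserves (3, 6, 9 km), land-class score, and NDVI (0.3, 0.5,
0.7). Water sensitivity overlays distance to water bodies (0.5, 1, 1.5 km),
to wastewater sources (3, 6, 9 km) and to air-pollution sources (4, 8,
12 km). How the sub-scores combine is not standardized; we use the
unweighted arithmetic mean, which keeps the 1–7 scale and adds no hidden
weighting (`combine = "sum"` is available). Soil loss is the multiplicative
equation $A = R \cdot K \cdot LS \cdot C \cdot P \cdot T$; the factor rasters
are pipeline inputs (the synthetic generator derives simple versions from
precipitation, terrain and NDVI), since computing erosivity or erodibility
from raw climate and soil archives is a real-data concern outside this
package's scope. Soil loss is min-max normalized before integration, like
the other two layers, so its absolute scale cannot dominate the overlay.

## Sources

Ecological importance is $0.5\,\mathrm{norm}(services) +
0.5\,\mathrm{norm}(sensitivity)$, classified into quartiles. Candidate source
cells are the top class ("extremely important"; configurable to the top two)
unioned with the statutory red-line polygons. Candidates are split into
8-connected patches and patches under `min_area_km2` (default 10) are
dropped — small patches radiate little and connect poorly — *unless* they
intersect the red line: statutory reserves are kept wholesale, whatever their
size, which mirrors how red-line areas dominate source selections in
practice. Quantile ties go to the lower class, so classification is a
deterministic monotone step function.

## Resistance surface

Six factors are classified to resistance values and combined as
$R = \sum_f w_f \cdot \mathrm{class}_f$ with weights 0.30 (land class),
0.15 (relief), 0.15 (slope), 0.15 (class-I road distance), 0.15 (class-II
road distance), 0.10 (pollution distance). Land-class values range from 1
(forest) to 1000 (mine); the interval factors step from 100 down to 1. The
analytic range is $[1, 370]$: 1 when every factor sits in its most permeable
class, 370 for a mine pixel with every other factor at 100. Values above the
last printed interval (relief > 239 m, slope > 47°) clamp into the last
class. The published pollution table skips the 4–6 km band; we read the
60-resistance class as covering (4, 8] km — the only gap-free reading that
preserves five classes.

## Connectivity

Valid cells form an 8-neighbor graph; moving between adjacent cells costs the
mean of the two cell resistances times the center-to-center distance
(× $\sqrt2$ for diagonals), the standard raster-graph convention.

* **Cost-weighted distance (CWD)** is a multi-source Dijkstra from all patch
  cells (implemented in C++; verified against an independent igraph oracle
  and exhaustive path enumeration at tiny sizes).
* **Corridors.** For each retained pair, the least-cost path (LCP) is
  backtracked through the CWD field; the swath is
  $CWD_A + CWD_B - lcp \le \theta$. We default $\theta$ to half the corridor
  width times the minimum landscape resistance, which makes the swath about
  1 km wide near the patches on a uniform landscape — corridors are also
  emitted as fixed 1-km buffers of the LCP for the land-composition report,
  since 1 km is the widely used width covering the dispersal range of most
  terrestrial species. Pairing follows the pruned-adjacency rule used by
  corridor-mapping practice: mutually-nearest pairs plus every pair whose LCP
  does not cross a third source (all-pairs is available); building all
  $O(n^2)$ corridors would count the same physical route many times.
* **Circuit theory.** Conductance is 1/resistance; the two patches collapse
  to supernodes, 1 A is injected and withdrawn, and the grounded Laplacian is
  solved with sparse linear algebra. Per-cell current is half the sum of
  absolute incident edge currents. Solutions conserve current at every
  interior node to < 1e-8 of the injection (checked in the tests), and
  effective resistance can never exceed the LCP resistance.
* **Pinch points** score each swath cell by the maximum pairwise current it
  carries. The top-n cells are reported after non-maximum suppression with a
  1-km radius, so "top 40" means 40 distinct locations; ties break on cell
  index, deterministically. Whether published priority scores are pairwise or
  cumulative currents is ambiguous; we use the pairwise maximum, which is
  what makes a narrow crossing stand out.
* **Barriers.** A moving window (radii from 200 m — at least one cell — to
  1000 m, stepping one cell) is restored to the landscape's minimum
  resistance, the pair's least-cost cost is recomputed (incremental
  early-exit Dijkstra), and the improvement score is
  $IS = \Delta cost/(2\,\mathrm{radius})$ — per metre of window diameter, one
  of the two normalizations in circulation; it is a single constant away from
  the per-radius variant. Window centers are the corridor swath cells
  (optionally strided for speed); IS is zero wherever the landscape is
  already at minimum resistance.
* **Centrality.** The coarse network (one node per source, link resistance =
  corridor LCP cost) is solved for every node pair; accumulated absolute
  currents give corridor and source centrality.
* **Priority.** Corridor improvement levels (quantile classes of zonal mean
  IS) are cross-tabulated with priority levels (quantile classes of zonal max
  current) into L/M/H/V × L/M/H/V; the V&V cell marks the priority
  corridors.

## The synthetic landscape generator

`generate_landscape()` emulates the *structure* of regional GIS inputs:
land-cover classes are carved from a Gaussian-smoothed white-noise field
thresholded at the cumulative class proportions (giving spatially clustered
classes whose realized shares match the request up to ties); the DEM is a
band-limited field scaled to a requested relief; precipitation and NDVI are
smooth fields; AET is precipitation times a smooth factor in [0.2, 0.9], so
water yield is positive and spatially structured by construction; roads are
jittered edge-to-edge polylines, pollution plants uniform points (typed
wastewater/air), reserves circular polygons. Defaults mirror a
cropland-dominated alluvial plain (≈62% cropland, 16% forest, 13% water,
8% built-up).

What it does *not* emulate: hydrological realism (rivers are a land class,
not a drainage network), road-network topology, correlated threat placement
(industry clusters near cities in reality), or any calibrated regional
statistics. Tests passing on these landscapes therefore demonstrate the
*correctness of the algorithms* — distances, overlays, solves, scans — and
the end-to-end plumbing, not that real-data results would be numerically
reproduced.

Four designed fixtures carry planted structure for tests: `uniform` (one
class, flat — resistance must come out constant), `two_patch` (reserves at
opposite corners), `hourglass` (two low-resistance blocks joined by a
1-cell bridge in a matrix 10⁴ times more resistant, so the bridge must be the
rank-1 pinch point carrying ≈ the whole injected ampere; the contrast keeps
matrix leakage around 2–3%), and `wall` (a 3-cell high-resistance strip with
no gap, whose best barrier window and improvement score are hand-computable
on a 1-D transect).

## Numerical and scaling choices

Distances are exact Euclidean (a two-pass distance transform); an empty
target set (no pollution plants, say) yields infinite distances, which land
in the most permissive score or resistance class. The relief window defaults
to 3 × 3 cells. Degenerate inputs are defined, not fatal: constant rasters
normalize to zero with a warning and classify as a single low class; a single
corridor gets the lowest priority labels.

Problem sizes are chosen for desk-scale runs: the demo pipeline is a
120 × 120 grid at 100 m (a 12 × 12 km landscape, ~4 s end to end), the
planted-structure checks run at 200 × 200, oracle comparisons at ≤ 6 × 6
against exhaustive or dense references, and the demo source-area floor is
2 km² (the 10 km² default belongs to region-scale maps hundreds of km
across). The acceptance script reports the analytic minimum of the
resistance overlay, which is scale-free.

## Known limitations

* Circuit analyses are pairwise between corridor endpoints; all-to-ground
  modes and species-specific dispersal kernels are out of scope.
* The barrier scan re-runs an early-exit Dijkstra per window; on large grids
  use `barrier_stride` to thin candidate centers.
* Raster I/O is Esri ASCII grid and vector I/O is GeoJSON — portable text
  formats any GIS reads; there is no CRS handling or reprojection.
* Parameter defaults (threat weights and distances, habitat sensitivities,
  carbon pools) are field-plausible editable tables (`inst/extdata/*.csv`),
  not calibrated values; any regional application must supply its own.
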