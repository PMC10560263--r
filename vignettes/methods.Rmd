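---
title: "Modelling travel-time access and workforce coverage with hfaccess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling travel-time access and workforce coverage with hfaccess}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfaccess)
```

## The problem

Primary-care networks in sparsely settled regions are organised in two
tiers: health posts (HPs), small preventive-care units run by health
extension workers (HEWs), and health centers (HCs), which provide curative
care and receive referrals from roughly five to eight HPs each. Whether a
household can actually use this system depends jointly on geography (can
they reach a facility in an hour or two of walking?) and on staffing (is
anyone qualified there when they arrive?). `hfaccess` computes both sides
on one analysis grid and joins them.

## Travel model

**Merged landcover.** All layers are aligned to a single square-cell grid
in a projected metric CRS. Base landcover (bare, shrubland, built, water)
is overlaid with vector layers at a fixed precedence: roads beat water,
water beats the base class. Rivers and lakes are rasterized as full
barriers; a cell crossed by both a road and a river keeps the road class
and is the bridge — passable by construction. Rasterization is
*all-touched* (a cell is marked when the geometry intersects it, not only
when its center is covered). The alternative center-in rule leaves
one-cell gaps in thin diagonal barriers, which would let travellers walk
through rivers; all-touched keeps linear barriers hydrologically closed at
the cost of slightly overstating their width at a ~100 m grid. Both facts
are consequences of rasterizing line features near the cell size, and the
wider-river bias is the conservative direction for an accessibility study.

**Step costs.** Travel is modelled on the 8-connected cell graph
(4-connectivity is available for cross-checks). A step from cell *a* to
cell *b* of planar length *d* (cell size, ×√2 diagonally) costs
`d/2 · (1/v_a + 1/v_b)` minutes: each cell contributes half the step at
its own effective speed. This half-cell convention is the standard
cost-distance discretization; it is exact for homogeneous neighbours and
symmetric whenever speeds are direction-independent.

**Slope.** Walking speed is multiplied by the normalized Tobler hiking
factor `exp(−3.5·|s + 0.05|)/exp(−3.5·0.05)`, where `s` is rise over run
in the direction of motion. The normalization makes flat ground return
exactly the configured class speed, so the flat-terrain behaviour of the
model is independent of whether the correction is enabled — a property the
test suite asserts bit-for-bit. The factor peaks at the gentle downhill
`s = −0.05` (≈1.19) and decays on both sides; motorized speeds are not
slope-corrected. Whether a given historical analysis ran its walking
scenario anisotropically is usually unknowable from publications; both
settings are first-class here (`slope_correction = "tobler_normalized"` or
`"none"`), and population-to-facility travel evaluates edges in the
direction of the facility (`direction = "to_facility"`), which only
matters when the correction is on.

**Accumulation.** Multi-source shortest paths are computed with Dijkstra's
algorithm (via igraph) from all facilities of a set; the per-cell minimum
is the travel-time surface and the argmin is the cost-allocation raster
("full catchment" partition). Ties go to the lowest facility index. Cells
that reach no facility — including barrier cells — carry infinite time and
no allocation. The engine is verified against an independently coded
Bellman–Ford oracle on dozens of random mixed-mode landscapes up to 40×40
cells at a relative tolerance of 1e−9.

**Scenarios.** A scenario maps each passable class to `{mode, speed}`.
The shipped defaults are placeholders plausible for an arid rural region
— walking 3–5 km/h by class, vehicles 25–60 km/h on roads — and are
configuration, not findings; real studies should load their own YAML
(`read_scenario()`). The walk→vehicle transfer is free by default because
the motorized scenario assumes a readily available vehicle at the road; a
per-transfer penalty parameter exists (minutes, default 0).

## Catchments and coverage

A cell's population counts toward facility *f* at threshold τ iff the
allocation assigns the cell to *f* and its travel time is ≤ τ. Thresholded
catchments therefore nest inside the full allocation catchment and never
overlap, making per-facility populations additive — their sum over
facilities equals the reachable population exactly, which the tests assert
as an invariant. An overlapping-isochrone variant
(`facility_isochrone_population()`) exists for sensitivity analysis, since
published per-facility catchment populations do not always state which
convention they used; under the non-overlap convention the union of HC
catchments and the sum of per-HC allocation catchments coincide, so the
distinction only matters in the overlapping mode. Population on
unreachable cells is uncovered at every threshold. Zones (districts) are
carried as a zone-id raster and a cell belongs to the zone at its center,
ties to the lowest id. Catchment populations are classified into
closed-left bands (`[2000, 5000)`, `[15000, 25000)`, ...), the latter being
the planning band an HC is intended to serve.

## Referrals and restructuring

Referral analysis runs HP→HC under a walking-only scenario (referral
travel in such settings is predominantly on foot). Each HP's referral time
is the HC-set cost surface evaluated at its cell — asserted exactly — and
its travelled distance is the summed planar step lengths along the
backtraced least-cost path, whose re-costed edge sum must match the
accumulated time within 1e−6 relative. Classification thresholds: within
2 km of the HC a merge candidate, within 10 km basic, beyond 10 km a
comprehensive-HP candidate, with closed "within" bounds (exactly 10 km is
basic). The package classifies on the *travelled* distance by default:
straight-line proximity misrepresents what a referral costs whenever the
path detours around barriers, and travelled kilometres are the quantity a
patient actually walks. Because restructuring guidance may intend
straight-line distance, `distance_basis = "straight"` is available, and
both distances are reported per link. Referrals cross district borders by
default; `mode = "within_district"` restricts each HP to its own
district's HCs, reproducing implementation rules that forbid crossing.

## Workforce benchmarking

Three comparisons, in decreasing spatial resolution:

* **Per-HC minima** — each cadre's headcount against a per-HC minimum
  table; below is understaffed (deficit = min − count), equal adequate,
  above overstaffed; a facility is *fully adequate* only with zero
  understaffed cadres.
* **Density benchmarks** — cadres are reclassified into groups, pooled
  over HCs, and divided by the population within 1 h / 2 h of any HC, per
  10,000. Required headcounts use a ceiling (fractional workers cannot be
  hired) and the additional need is floored at zero. The per-HC planning
  band (15,000–25,000) is deliberately *not* used to scale the minima —
  one minimum table applies to every HC.
* **HEW gaps** — per district, shortage `Σ max(0, 2 − hew)` and surplus
  `Σ max(0, hew − 2)` over HPs, reported separately and never netted: a
  surplus worker in one district cannot staff another. The tests pin this
  with the `[0,1,2,3] → shortage 3, surplus 1` fixture.

All benchmark numbers (cadre list, minima, densities, the 2-HEW norm) ship
as editable YAML with placeholder defaults marked non-authoritative.

## The synthetic scene generator

`generate_scene()` produces, from one integer seed, a fully
self-consistent study area: a smoothed-noise DEM (400–700 m relief);
landcover from a second smoothed field; lakes; population allocated to
settlements with log-normal sizes and spread by a Gaussian kernel
(conserving the configured total to within one person per settlement);
roads as the minimum spanning tree over settlement centers; rivers as
random walks crossing the scene, each road crossing bridged independently
with probability `bridge_probability` (an unbridged crossing physically
interrupts the road geometry, so the barrier stays closed); districts as
the nearest-seed planar partition; HCs at the largest settlements; HPs at
a *random* subset of settlements plus rural cells — facility siting in
practice does not track settlement size, and making it do so would
overstate coverage; staffing drawn around the benchmark minima with
deficits at the configured rate.

Default conditions (chosen once for structural realism): a 160×160 grid of
100 m cells (≈16 km × 16 km), 50 settlements, 3 HCs and 30 HPs (the ~10:1
HP:HC ratio of two-tier networks), 8 districts, 3 rivers with 40% bridge
probability, 150,000 people, 60% staffing-deficit rate. What the generator
deliberately does **not** emulate: regional-scale facility sparsity. A real
region may average hundreds of km² per facility; a desk-scale scene at
100 m resolution cannot, so the combined HP+HC network covers most of the
synthetic population within 1 h and the informative gradients appear in the
HC-only results, the referral distances and the staffing tables. Passing
tests therefore demonstrate the correctness and invariances of the method
— conservation, nesting, monotonicity, barrier semantics, oracle
equivalence — not the magnitude of any real region's coverage gap. Also
out of scope: seasonal or nomadic population movement, travel behaviour
(bypassing the nearest facility), congestion, and hydrological realism.

## Numerical conventions

* Grid indexing is 1-based (row, col) with row 1 at the north edge; world
  ↔ cell via the affine georeference, cells identified by centers.
* Travel time is double-precision minutes; thresholds default to 60, 120,
  180. Unreachable is `Inf` in memory and nodata on disk (ASCII grids
  cannot hold `Inf`).
* Facility snapping relocates any facility on a barrier, nodata or
  out-of-extent cell to the nearest passable cell by Euclidean
  center-to-center distance, ties broken row-major (smallest row, then
  column); snapping is idempotent and the relocation distance is logged.
  The snapping metric and the rasterization rule are both configurable
  design decisions, since upstream tools rarely document theirs.
* Rasters are serialized as ESRI ASCII grids with `%.17g` precision, so
  write/read round trips are exact; vectors as GeoJSON; the CRS and scene
  config live in a JSON manifest. Text formats keep every artifact
  diffable and the pipeline runs byte-reproducible (SHA-256 manifest).
* Scenario comparison is infinity-aware: `Inf − finite = Inf`,
  `Inf − Inf = nodata`.

## Test problem sizes

The suite runs micro-scenes with hand-computable answers (1×3 corridors,
5×5 river worlds), 50 random landscapes up to 40×40 cells against the
Bellman–Ford oracle, full synthetic scenes of 40–60 cells a side for the
conservation/nesting/monotonicity properties, and 40×40 end-to-end
pipeline runs for determinism; the acceptance script runs the default
160×160 scene. These sizes keep the whole suite in the tens of seconds
while exercising every code path; all properties are scale-free.

## Known limitations

Travel times inherit every simplification of the friction model: no
congestion, ferries, seasonal road states or waiting times, and a single
speed per class. The Tobler correction is a population-average walking
law, not a fit to local data. Coverage treats facilities as points with
unlimited throughput — the workforce module exists precisely because that
assumption is false in the staffing dimension. District apportionment of
additional workers is proportional to covered population, which is one of
several defensible rules. The generator's landscapes are statistically
plausible but not hydrologically consistent (rivers ignore the DEM).
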