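---
title: "Modelling dispersal corridors and climate-stability refugia with paleocorridor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dispersal corridors and climate-stability refugia with paleocorridor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Middle Palaeolithic Neanderthal groups with distinct techno-complexes
(Micoquian in the Greater Caucasus, Mousterian in the Lesser Caucasus)
appear again, with the same cultural signatures, thousands of kilometres
east in the Siberian Altai. Reconstructing *how* they got there is a
spatial problem: the Caspian Sea — the world's largest closed basin —
sits squarely between the Caucasus and Central Asia, so any eastward
dispersal must round it either across the northern plains or through the
narrow strip between the Alborz Mountains and the southern shore (the
Southern Caspian Corridor, SCC). Which way is open, and how wide the
coastal strip is, depends on the sea's stand at the time: the basin is
closed, so its level swings by tens to hundreds of metres between glacial
and interglacial stages.

`paleocorridor` implements that model as a tested pipeline:

1. **Terrain**: slope from a DEM (Horn's method) — slope is the cost driver.
2. **Barriers**: flood-filled sea stands, desert polygons, an elevation
   suitability band, composable into masks.
3. **Routing**: least-cost paths on the 8-connected raster lattice
   (deterministic Dijkstra, great-circle edge lengths).
4. **Corridor**: a 30 km settlement-potential buffer around routes with
   site membership reporting.
5. **Climate stability**: temperature-change velocity between two epochs
   (Last Interglacial to Last Glacial Maximum analog) nominating refugia.
6. **Synthetic data**: a seeded generator of landscapes with the study
   geography, so the whole pipeline runs and is tested with no downloads.

## Data model

Every raster travels as a `GeoGrid`: a north-up matrix with the NW corner
of cell (1,1) at (`xOrigin`, `yOrigin`) in decimal degrees, square cells
of `cellSize` degrees, and `NA` for nodata in memory (the on-disk sentinel
is kept alongside). Only geographic WGS84 grids are supported; anisotropic
ground distance is handled at edge-weight time rather than by
reprojection, which keeps the model faithful to the lat/lon rasters the
field actually uses (SRTM, PaleoClim, CHELSA). I/O covers the ESRI ASCII
grid (written with 6 significant digits — the documented bit-exactness
boundary for round trips) and a minimal uncompressed single-band GeoTIFF.
`alignTo()` resamples (nearest or bilinear) onto a reference geometry to
co-register climate layers with the DEM.

## Slope and movement cost

Slope at each interior cell comes from Horn's third-order finite
difference over the 3x3 neighborhood, `slope = atan(sqrt(p^2 + q^2))`,
with metric spacings `dy = cellSize * 111320 m` and
`dx = dy * cos(lat)` *per cell row*: the study area spans tens of degrees
of latitude, and a single scalar `dx` would bias eastern and northern
slopes. Border cells (and any cell with a nodata stencil neighbor) are
nodata so that routing cannot exploit artificially flat borders.

The movement-cost surface is `cost = 1 + k_slope * slope_degrees`,
defaulting to `k_slope = 0.1` (cost doubles at 10 degrees). The source
model states only that higher slope means higher cost; the linear form is
the minimal monotone assumption, and `k_slope` is exposed in every entry
point. Tobler's hiking function is available behind the same contract
(`costFunction = "tobler"`, cost as reciprocal relative walking speed,
normalised to 1 on flat ground), off by default. Blocked and nodata cells
get `Inf`: they are absolute barriers, not large costs (a finite
`desertCostMultiplier` is available for sensitivity analyses).

## Barriers and sea stands

Because the basin is closed, inundation is *connectivity-limited*: a cell
floods only if it lies at or below the stand **and** is 4-connected to
the sea seed. Depressions below the stand that do not connect stay dry.
4-connectivity is deliberate: it prevents the sea leaking diagonally
through one-cell land bridges that 8-connected routing could not cross
anyway. The published stands ship as presets (`caspianStands()`): present
-27 m, Late Khazarian -10 m, the Atelian lowstand as both published
endpoints -120 and -140 m (the source gives a range, so both ship rather
than guessing one), and Early Khvalynian +50 m.

The suitability band [50, 1800] m asl encodes two facts: the +50 m
transgression likely destroyed any settlement trace below 50 m, and
settlement density drops above ~1800 m. The band is a *closed* interval —
"less than 50 m" is unsuitable and "up until 1800 m" suitable, which
forces boundary cells open. `applyBand` defaults to off for
continental-scale routing (the northern route legitimately crosses plains
below 50 m); the band delimits the corridor habitat zone and is applied
when tracing within it. Deserts are polygons rasterised by the even-odd
rule on cell centers (holes work naturally; self-intersecting rings are
rejected).

## Routing

`leastCostPath()` runs Dijkstra on the 8-connected lattice with edge
weight `d(i,j) * (cost_i + cost_j) / 2` — the trapezoidal transition rule
of the `gdistance` tooling family — where `d` is the great-circle
distance between cell centers (mean Earth radius 6371.0088 km). Equal-cost
ties are resolved toward the lexicographically smallest predecessor
(row, then column), which makes outputs byte-reproducible. Endpoints snap
to their containing cell center; a blocked endpoint raises a placement
error rather than snapping to the nearest open cell, because silent
snapping can jump a barrier. A fully severed pair raises an unreachable
error — this is a *finding*, not a failure: it is the
populations-lost-connection regime of the transgression scenarios.

On a uniform cost surface the lattice geometry elongates routes by at
most ~8% over the straight great circle (the known 8-connected bound);
the suite asserts this, and verifies total costs against an exhaustive
Bellman-Ford relaxation on 100 seeded grids to 1e-9 relative.

## Corridor buffer

The corridor is the set of points within `bufferKm` (default 30 km) of
the route *polyline*: cross-track great-circle distance to segments,
clipped to segment extent, falling back to vertex distance beyond the
ends. Vertex-only distance over-excludes on coarse rasters (a point near
a long segment's midpoint can be hundreds of km from both vertices); the
suite keeps a regression test for exactly that bug. Whether the published
30 km was ground or planimetric is unstated; ground (great-circle)
distance is used and documented here. Site reports include each site's
distance so users can re-threshold without recomputation.

## Climate-change velocity

Velocity is the speed an organism must move to keep its temperature
constant: the temporal rate `|t_new - t_old| / delta_years` divided by
the local spatial gradient magnitude (same Horn stencil, metric
distances), converted to km/century. Three numerical choices matter:

- `gradientSource` defaults to `"old"` (the earlier epoch's gradient);
  the computation is named in the source but not the layer, so all three
  options (`old`, `new`, `mean`) are exposed.
- Flat-field division is the classic failure mode of velocity maps:
  cells with gradient below `gFloor` (1e-6 degC/km) deterministically
  receive the ceiling `vCap` (10000 km/century), and everything is
  clamped to `[0, vCap]`.
- `stabilityMask()` keeps the lowest-velocity fraction `q` of cells as
  refugia using the inclusive rank threshold `round(q * n)`, so ties are
  stable rather than arbitrary (all-equal fields are entirely stable).

Epoch "mapping" beyond the velocity computation reduces to reading the
grids, `alignTo()` onto the DEM and `gridSummary()` over a region mask;
cartographic rendering is out of scope.

## The synthetic landscape: what it emulates and what it does not

`generateLandscape()` builds, deterministically per seed: two east-west
Gaussian ridges (northern crest 48N, 2500 m; southern crest 34.5N,
3000 m) on 150 m plains over a 200 x 400 grid of 0.1-degree cells
(lon 40-80, lat 30-50); a closed elliptical sea basin (center 47E 41N,
semi-axes 8 x 4.5 degrees) with a parabolic bowl to -200 m — below every
published stand — and a gentle shelf ring whose exposure varies strongly
between stands; a low coastal strip at ~30 m asl between the southern
ridge and the basin (the SCC analog, 8 cells wide), connected to the
basin by a channel so that transgressions drown it; two desert lobes east
of the sea flanking the strip (Karakum analog north of it, an
inner-desert analog south of it); and knolls that keep the mid-corridor
waypoint and the eastern terminus above the strip floor. Terrain noise is
band-limited (Gaussian-filtered white noise, sd 10 m, ~3-cell
correlation), not per-cell white noise, so slope fields are realistic and
flood fill is stable.

This geometry reproduces the model's qualitative headline testably: both
a northern and a southern route exist; with the deserts active the
southern route is confined to the corridor strip; removing the deserts
never increases its cost; and raising the stand to +50 m drowns the strip
(including the land around the eastern terminus) and severs the southern
route entirely. The severance mechanism is worth stating: with band masks
off, a mountain can never sever an 8-connected route — only water,
deserts and the grid margin can — so the corridor floor lies below +50 m
and the transgression closes it, which is exactly the source's argument.

What the generator does **not** emulate: the true orography of the
Caucasus/Alborz/Altai, river systems and deltas, tectonic subsidence, or
paleoclimate beyond a lapse-rate temperature field with uniform epochal
cooling. A green scenario test therefore establishes the *topological*
behavior of the model under the stated barrier hypotheses, not a
prediction for the real landscape.

`generateClimate()` lays temperature over the DEM at a 6.5 degC/km lapse
from 15 degC at datum, cools the newer epoch by 5 degC (a glacial-scale
mid-latitude cooling), with optional independent white noise per epoch.
On this construction velocity is lowest where terrain is steepest, which
the suite asserts as a negative Spearman rank correlation between slope
and velocity — the mountain-refugium behavior claimed for the corridor.

## Orchestration and provenance

`runScenario()` drives a whole scenario from one config (YAML or list):
inputs (files or synthetic seed), slope, masks, cost surface, every
configured route, corridor CSVs, optional velocity/refugia maps, and a
JSON manifest with per-route numbers, input MD5 hashes and the package
version. Validation is fail-fast (an unknown site name aborts before any
output is written) and the manifest carries no timestamps, so identical
configs produce byte-identical outputs — the determinism the source
workflow (interactive GIS layering) could not offer.

## Known limitations

- Single-band geographic rasters only; no reprojection, no rotated grids.
- The GeoTIFF dialect is deliberately minimal (uncompressed strips,
  one band); foreign variants are rejected loudly rather than misread.
- Costs are isotropic; direction-dependent effort (uphill vs downhill)
  and circuit-theory connectivity are out of scope.
- Velocity is univariate (temperature); precipitation enters only as a
  reported summary layer.
- The exact cost formula and slope coefficient of the source workflow are
  unrecoverable from its text; only the monotone slope-cost relation is
  modelled, with `k_slope` exposed rather than inferred.
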