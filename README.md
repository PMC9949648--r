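# paleocorridor

Least-cost-path dispersal corridors and climate-stability refugia on
raster landscapes.

## What this is for

Middle Palaeolithic Neanderthal groups with distinct techno-complexes
(Micoquian, Mousterian) occur both in the Caucasus and, far to the east,
in the Siberian Altai. Between them lies the Caspian Sea — a closed basin
whose level swung between roughly −140 m (Atelian lowstand, MIS 4) and
+50 m (Early Khvalynian highstand) — flanked by the Karakum desert and
the Alborz Mountains. Eastward dispersal must round the basin either
across the northern plains or through the narrow Southern Caspian
Corridor (SCC) between the mountains and the southern shore, and which
way is open depends on sea stand, desert extent and terrain.

`paleocorridor` turns that verbal model into a reproducible computation
for paleobiogeographers and archaeologists:

- **slope-based cost surfaces** from a DEM: Horn slope, then
  `cost = 1 + k_slope · slope°` (default `k_slope = 0.1`; Tobler's hiking
  function available behind the same contract);
- **barrier masks** from paleogeographic hypotheses: connectivity-limited
  flood fill of the closed basin at a chosen stand, desert polygons
  (even-odd rule), the [50, 1800] m asl suitability band;
- **least-cost routing**: Dijkstra on the 8-connected lattice with edge
  weight `d(i,j) · (cost_i + cost_j)/2`, `d` the great-circle distance
  between cell centers, deterministic tie-breaking;
- **corridor buffers**: the 30 km settlement-potential zone around a
  route with per-site cross-track distances;
- **climate-change velocity** between two epochs,
  `v = (|ΔT|/Δt) / |∇T|` in km/century, with deterministic capping of
  flat-gradient cells and a quantile stability mask nominating refugia;
- a **seeded synthetic landscape generator** that emulates the
  Caucasus–Caspian–Altai geography, so the full pipeline runs and is
  tested without any data downloads.

Rasters are ESRI ASCII grids or plain single-band GeoTIFFs; sites are
CSV; scenarios are YAML; paths and polygons are GeoJSON.

## Worked example

```r
library(paleocorridor)

land <- generateLandscape(landscapeParams(seed = 7))
land$dem
#> GeoGrid: 200 x 400 cells of 0.1 deg, NW corner (40, 50)
#>   values: min -200 / mean 545.6 / max 3185, 0 nodata cell(s)

slope <- computeSlope(land$dem)
cost  <- buildCostSurface(slope, scenarioMask(land$dem, land$scenario),
                          scenarioName = land$scenario@name)
south <- leastCostPath(cost, c(43.5, 35.5), c(79.3, 35.5),
                       startName = "SouthwestCave", endName = "EastCave",
                       scenarioName = land$scenario@name)
south
#> DispersalPath SouthwestCave -> EastCave (MIS4-Atelian): 358 cells,
#> total cost 3253, length 3240.4 km

sitesInCorridor(land$sites, bufferCorridor(south, 30))
#>                 name  lon  lat    culture      role distance_km
#> 1 MidCorridorShelter 62.0 35.5 Mousterian  waypoint    5.560902
#> 2      SouthwestCave 43.5 35.5 Mousterian     start    7.020254
#> 3           EastCave 79.3 35.5      other       end    7.170135
#> 4        CoastalCamp 46.0 35.4      other candidate   16.680410
```

The route runs under the Atelian (−140 m) stand with both desert lobes
active: 358 cells, 3240 km of great-circle length, accumulated cost 3253
cost·km (cost ≥ 1 everywhere, so cost can never fall below length). All
of its cells lie in the coastal corridor strip between the sea mask and
the 1800 m contour. Four sites fall inside the 30 km buffer, ordered by
their cross-track distance to the route; the endpoints sit a few km off
because they are reported from cell centers on a 0.1° grid. Re-running
the same scenario at the +50 m Khvalynian stand drowns the strip and
raises a `pcUnreachableError` — the regime in which the populations on
either side lose their connection.

`runScenario()` drives the same computation (plus the velocity/refugium
map) from a single YAML or list config and writes a manifest with input
hashes; `inst/scripts/paleocorridor.R` exposes `slope`, `lcp`,
`corridor`, `velocity`, `simulate` and `run` subcommands over the same
functions.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end to end against the installed package:
generates the seeded synthetic landscape and climate epochs, builds the
cost surface under the default scenario, solves the northern and
southern routes, reports corridor membership, computes the velocity map
and refugium mask, and logs per-stage cell counts and timings before
writing the JSON report to `--out`.

## Package layout

- `R/` — S4 classes (`GeoGrid`, `Mask`, `BarrierScenario`, `CostSurface`,
  `DispersalPath`, `Corridor`, `ClimateEpochPair`, `VelocityGrid`) and
  the module functions; `src/` — the Dijkstra core (Rcpp).
- `vignettes/paleocorridor-methods.Rmd` — the model, its assumptions,
  parameter choices and limitations.
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (exhaustive Bellman–Ford, queue-based flood fill,
  closed-form geodesy).
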