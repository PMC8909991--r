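---
title: "Measuring residential-scale equity of public sports space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring residential-scale equity of public sports space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equicity)
```

## The problem and the model

Access to public sports space — parks, squares, fitness centers and sports
fields — is tied to physical activity and public health, and is rarely
distributed evenly across a city. `equicity` quantifies that inequality at
the finest residential scale: each residential building receives an equity
score per facility category, under two travel modes that together bracket
everyday access — a 15-minute walking circle and a 30-minute bus circle.

For building $j$ under the walking mode, the score is a decay-weighted sum
over the facilities of a category reachable within the time horizon $t_0$:

$$A_j \;=\; \sum_{i\,:\,t_{ij}\le t_0} S_i\, P_i\, G(t_{ij}),
\qquad G(t) = e^{-\tfrac12 (t/t_0)^2},$$

where $t_{ij}$ is the door-to-door shortest-path walking time on the road
network, $S_i \in \{1,\dots,5\}$ is the facility's service-capability grade
(encoding its size or level), and $P_i \in [1,5]$ is a crowd-sourced
attractiveness score. $G$ is a simplified Gaussian time-decay kernel: a
facility at your doorstep counts fully, one at the edge of the time circle
counts $e^{-1/2} \approx 0.61$ as much.

The bus-mode score uses the same form with two changes: the travel time is
composed from three legs,

$$T_{ij} = w_i + p_{ij} + w_j,$$

and each term in the sum is additionally multiplied by $N_i \, N_j$. Here
$N_j$ and $w_j$ are the number of bus stops within 600 m walking distance
of the building and the mean walking time to them; $N_i$ and $w_i$ are the
same for stops within 400 m of the facility; and $p_{ij}$ is the
in-vehicle time of the best connection — the minimum shortest-path time at
bus speed over all pairs of stops drawn from the two catchments. The decay
kernel uses the bus horizon ($t_0 = 30$ min). A building or facility with
no stop in range contributes nothing to the bus mode. The stop-count
multiplier is applied exactly as the model prescribes, with no cap; it
deliberately rewards stop-rich locations, and consequences of that choice
are discussed under limitations.

Walking and bus scores are summed per category, the four categories are
standardized to equal importance, and a building's overall equity value is
the mean of its four standardized category scores.

## Travel times on the road network

Roads are ingested as planar-projected polylines and become an undirected
graph: vertices merge within a 0.5 m tolerance, consecutive vertices form
edges weighted by Euclidean length, and one-way restrictions are ignored
(pedestrians are direction-agnostic; the bus model is too coarse to use
them). Off-network points — buildings, facilities, stops — are snapped to
the nearest point on any edge; the snap point is inserted as a node
splitting its host edge, so path search starts exactly where the traveler
joins the network rather than at the nearest pre-existing junction. The
Euclidean leg from the door to the snap point is walked at walking speed
and added to every trip. Points farther than `max_snap_distance` (default
500 m) from every edge are flagged unreachable, excluded from scoring, and
listed — never silently dropped into a denominator.

Stop catchment radii (400 m / 600 m) are measured as network walking
distance by default, consistent with the network framing of everything
else; `mode_config(catchment_metric = "euclidean")` switches to
straight-line distance for comparison with buffer-style analyses.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `walk_speed` | 1.2 | m/s | walking legs and access/egress |
| `bus_speed` | 10/3.6 | m/s | in-vehicle leg (10 km/h) |
| `t0_walk` | 15 | min | walking horizon and decay scale |
| `t0_bus` | 30 | min | bus horizon and decay scale |
| `space_catchment_radius` | 400 | m | stops counted around a facility |
| `building_catchment_radius` | 600 | m | stops counted around a building |
| `max_snap_distance` | 500 | m | beyond this, off-network |
| `bus_window_low` | 0 | min | lower bound on bus trips admitted |

`bus_window_low` deserves a note. The summation condition of the bus-mode
formula admits every trip up to the horizon, while the surrounding prose
describes the bus circle as covering trips *between* 15 and 30 minutes.
The formula wins by default (`bus_window_low = 0`); setting
`bus_window_low = 15` reproduces the prose reading. Both behaviors are
exercised in the test suite.

The bus model is deliberately simple: it runs on the road graph at a
constant speed with no route topology, transfers, headways or waiting
time. This matches the coarse, general estimate the underlying method
makes; timetable-based transit routing is out of scope.

## Standardization

The four categories are declared equally important, but the model does not
pin down the transform that achieves this. The package defaults to the
weakest transform meeting the stated goal, `mean_equalize`: each
category's combined scores are scaled by (grand mean of the four category
means)/(that category's mean). All category means become equal while
every within-category ratio — who has twice as much as whom — is
untouched. After it, the maximum relative deviation of any category mean
from the grand mean is below 1e-9 by construction, and the overall value
(the mean of the four standardized scores) lives on the same scale as the
categories. Two documented alternatives, per-category min-max to 0–100 and
shifted z-scores, are selectable; the scheme used is recorded in the
result and in exported metadata. A category whose scores are all zero has
no defined rescaling and is left at zero with a warning.

## The synthetic city

Real inputs of this kind (commercial POI layers, vectorized building
footprints, review-platform scores) are proprietary, so the package ships
a seeded generator that reproduces the statistical structure the analysis
assumes, at desk scale:

* a connected street grid over a 2 km × 2 km extent at 200 m pitch, node
  positions jittered by a fraction (default 0.15) of the pitch — irregular
  enough to avoid lattice artifacts, connected by construction (a spanning
  check with nearest-component re-linking is enforced anyway);
* 400 residential buildings, by default spread uniformly over the extent.
  The central concentration characteristic of these data sits in the
  facilities, not the homes: with facilities clustered and buildings
  city-wide, most buildings lie in low-access areas, producing the
  right-skewed score distributions (mean > median) and the
  center-to-periphery attenuation the method is designed to expose. A
  `building_gradient` dial concentrates buildings toward the center for
  strongly monocentric scenarios — note that raising it compresses the
  very contrast under study, since homes then co-locate with the
  facilities;
* 40 facilities (8 parks, 8 squares, 12 fitness centers, 12 sports
  fields), each drawn from a mixture of a center-Gaussian (sd = extent/8)
  and a uniform component, weighted by the per-category
  `facility_clustering` (default 0.5; 1 = fully center-clustered).
  Capability grades follow a decreasing distribution
  (0.30, 0.25, 0.20, 0.15, 0.10 for grades 1–5): small neighborhood
  facilities outnumber flagship ones. Attractiveness is normal with mean
  3.5 and sd 0.8 truncated to [1, 5], mimicking the shape of
  review-platform scores, which pile up between 3 and 4.5;
* 2 bus routes, each the shortest network path between random peripheral
  nodes, with stops interpolated every 400 m — typical urban stop spacing.

Determinism is strict: one master seed, with per-layer sub-seeds so that
changing the building count does not perturb facility placement; the same
seed yields byte-identical layers. `plant_correlation_scenario()`
additionally co-locates a tunable share of facilities with bus stops,
providing a monotone (not exact) control of the walking-versus-bus score
correlation for testing the correlation analysis.

What the generator does **not** emulate: real street morphology (riverbeds,
ring roads, dead ends), building footprints and population weights,
route-constrained bus networks, and the sheer scale of a real central
urban area (thousands of facilities, tens of km). Tests passing on
synthetic cities therefore validate the mechanics and qualitative behavior
of the method, not any quantitative claim about a particular city. In
particular the desk-scale extent makes the 30-minute bus circle span the
whole city, so bus-mode variation is driven almost entirely by stop
proximity rather than by in-vehicle time.

## Downstream statistics

Per-category and overall distributions are summarized with exact sample
statistics (sample standard deviation, midpoint median; tables print to
one decimal, files keep full precision). The walking-versus-bus
relationship is Pearson's r per category on the raw per-mode scores
(standardization would distort the comparison of modes within a category),
with the two-sided p-value from the exact t transform on n − 2 degrees of
freedom; no multiple-testing correction is applied across the five
correlations, matching the method's usage. Zero-variance inputs yield a
flagged undefined-correlation row rather than an error, because a sparse
synthetic city can legitimately zero out one category's bus scores.
Quantile classification (ties to the lower class, boundaries reported)
supports choropleth-style mapping of the exported scores.

### Planning interventions

`run_intervention()` recomputes the full pipeline on a base and an
augmented dataset and reports per-category before/after summaries and
deltas. Both runs are summarized on combined scores rescaled by the
*base* run's mean-equalization factors: the intervention changes the
scores, not the yardstick. (Re-standardizing the augmented run would
partially absorb the intervention's effect into the scale itself.)

`propose_square_sites()` emulates the classic remediation — converting
vacant or under-used plots in deprived areas into squares. It selects
sites from the lowest decile of the overall score, spread by greedy
max–min distance (one site per deprived zone rather than five in the
worst one), and, when the stop layer is supplied, prefers locations
outside bus-stop catchments: the land stock this intervention draws on is
characteristic of weakly served areas, and a site inside a catchment
would act through the stop-count-multiplied bus term rather than through
neighborhood walking access.

## Numerical choices

* Vertex merge tolerance 0.5 m; snap ties broken by lowest edge id;
  coincident snap points (same edge, parameter within 1e-9 of each other)
  share one node, and snaps landing on an edge endpoint reuse it.
* Catchment radii and time horizons are compared with tiny tolerances
  (+1e-6 m, +1e-9 min) so that a stop exactly at 400 m, or a facility
  exactly at the horizon, is not dropped by floating-point noise from
  edge splitting.
* Geographic-looking coordinates (|x| ≤ 180, |y| ≤ 90) are refused at file
  ingestion with instructions to reproject; all distances assume planar
  meters. The heuristic applies only to file input, so small synthetic
  fixtures built in code are unaffected.
* The scoring pipeline itself consumes no randomness; only the generator
  holds seeds. Identical inputs give byte-identical exports.

## Problem sizes used in validation

The shipped test-suite exercises: exhaustive simple-path enumeration
against the routing on 200 random sparse connected graphs of up to 12
nodes; from-scratch score summation on 50 toy cities (≤ 15 nodes, 5
facilities, 4 stops); 100-trial monotonicity batteries (facility
additions, road additions, catchment growth); and ten-seed batches of the
full default synthetic city for the center–periphery, skewness and
intervention patterns. These sizes keep every property comfortably
testable on a laptop while leaving the patterns of interest clearly
resolved.

## A worked run

```{r example, eval = FALSE}
city <- generate_city(synthetic_city_config(seed = 1))
res <- run_pipeline(city)
res                      # per-category summaries, Table-2 style
res$correlations         # Pearson r, r^2, p per category and overall

sites <- propose_square_sites(res, n = 5, stops = city$stops)
added <- data.frame(id = paste0("new_", seq_len(nrow(sites))),
                    x = sites$x, y = sites$y, category = "square",
                    capability = 3, attractiveness = 3)
run_intervention(city, added)

write_results(res, "equity.geojson")   # one feature per building x category
```

## Known limitations

* The bus model ignores route topology, transfers, waiting and headways;
  it is a lower bound on real transit times.
* The uncapped $N_i N_j$ multiplier makes bus scores scale with the
  *square* of local stop density; in stop-sparse settings one added stop
  can move scores discontinuously.
* Facilities are points; a large park's extent is only encoded through
  its capability grade, not its geometry.
* No demand side: buildings are not population-weighted, and facilities
  have no capacity or congestion.
* Scores are relative within a dataset; standardized values are not
  comparable across datasets scored separately (use the intervention
  machinery, which freezes the yardstick, for before/after comparisons).
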