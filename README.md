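# equicity

Residential-scale measurement of how equitably public sports space —
parks, squares, fitness centers and sports fields — is distributed across
a city.

Planners, health geographers and urban researchers who want to know *which
homes* are under-served (not which census tracts) can feed the package
four standard vector layers — road centerlines, residential buildings,
sports facilities with a 1–5 service grade and a 1–5 crowd-sourced
attractiveness score, and bus stops — and get back a per-building,
per-category equity score under walking and bus travel, standardized
across categories, with distribution statistics, a walking-versus-bus
correlation analysis, and a before/after comparison tool for planning
interventions. A seeded synthetic-city generator makes the whole pipeline
runnable and testable without any proprietary data.

## The model

For building *j* and one facility category, the walking-mode equity score
is a Gaussian-decayed sum over the facilities reachable within the
15-minute walking circle:

    A_j = Σ_{i : t_ij ≤ t0}  S_i · P_i · G(t_ij),      G(t) = exp(−½ (t/t0)²)

with `t_ij` the door-to-door shortest-path walking time on the road
network (access leg + network path + egress leg at 1.2 m/s), `S_i` the
capability grade and `P_i` the attractiveness score. The bus mode uses
the same form with `t0` = 30 min, travel time composed as
`T_ij = w_i + p_ij + w_j` (mean walk to the stops within 600 m of the
building, best in-vehicle connection at 10 km/h, mean walk from the stops
within 400 m of the facility), and each term multiplied by the stop
counts `N_i · N_j`. Mode scores are summed, categories are standardized
to equal means, and the overall value is the mean of the four
standardized category scores.

## Worked example

```r
library(equicity)

city <- generate_city(synthetic_city_config(seed = 1))  # 2 km x 2 km, 400 buildings
res <- run_pipeline(city)
res
#> <equity_result> 400 buildings scored (0 excluded), scheme mean_equalize
#>        category   n mean median  std   max skew_flag
#>            park 400 49.4   25.3 46.1 151.1      TRUE
#>          square 400 49.4   49.3 30.8 108.8      TRUE
#>  fitness_center 400 49.4   48.1 36.4 119.5      TRUE
#>    sports_field 400 49.4   50.7 29.9 119.7     FALSE
#>         overall 400 49.4   47.6 25.6 115.5      TRUE
```

Every category mean equals 49.4 because `mean_equalize` standardization
makes the four categories equally important by construction; medians and
spreads still differ. `skew_flag` marks mean > median — many low-scoring
buildings, few high ones, the typical signature when facilities cluster
centrally while homes spread city-wide. `res$records` holds one row per
building × category (walk, bus, combined and standardized scores);
`res$correlations` gives Pearson r/r²/p between the two modes per
category (rows are flagged undefined when a sparse city zeroes out a
category's bus scores).

Emulate a planning intervention — five new squares on under-used land in
the lowest-scoring decile:

```r
sites <- propose_square_sites(res, n = 5, stops = city$stops)
added <- data.frame(id = paste0("new_", 1:5), x = sites$x, y = sites$y,
                    category = "square", capability = 3, attractiveness = 3)
run_intervention(city, added)
#> <intervention_report> +5 facilities, +0 stops
#>   park            delta mean +0.00, median +0.00, std +0.00
#>   square          delta mean +20.25, median +23.71, std -2.00
#>   fitness_center  delta mean +0.00, median +0.00, std +0.00
#>   sports_field    delta mean +0.00, median +0.00, std +0.00
```

The square category's mean rises and its standard deviation falls: the
intervention lifts the deprived tail. Other categories are untouched —
adding squares cannot change park access.

Results export to GeoJSON or CSV (one feature per building × category
plus an overall row, carrying building geometry for mapping in any GIS):

```r
write_results(res, "equity.geojson")
```

Real layers are read with `read_layers()` from GeoJSON or CSV in any
planar metric CRS; lon/lat input is refused with instructions to
reproject. A thin command-line front end
(`inst/cli/equicity.R generate | run | intervene | report`) wraps the same
functions for shell use.

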