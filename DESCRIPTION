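Package: equicity
Title: Residential-Scale Equity Measurement of Public Sports Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the spatial equity of access to public sports space
    (parks, squares, fitness centers, sports fields) at the scale of
    individual residential buildings. Travel times are computed on the road
    network for walking and a simplified bus mode; each building receives a
    Gaussian-decay accessibility score per facility category, weighted by
    facility service capability and crowd-sourced attractiveness, and the
    per-category scores are standardized and combined into an overall equity
    value. Includes a seeded synthetic-city generator so the full pipeline
    (ingestion, routing, scoring, descriptive statistics, walking-versus-bus
    correlation, and planning-intervention comparison) is exercisable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
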