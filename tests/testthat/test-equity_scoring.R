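cfg <- mode_config()

test_that("gaussian decay matches its closed form and decreases strictly", {
  expect_equal(gaussian_decay(0, 15), 1, tolerance = 1e-15)
  expect_equal(gaussian_decay(15, 15), exp(-0.5), tolerance = 1e-15)
  expect_equal(gaussian_decay(7.5, 15), exp(-1 / 8), tolerance = 1e-15)
  expect_equal(gaussian_decay(30, 30), exp(-0.5), tolerance = 1e-15)
  grid <- seq(0, 60, length.out = 500)
  expect_true(all(diff(gaussian_decay(grid, 15)) < 0))
  expect_error(gaussian_decay(-1, 15), "non-negative")
  expect_error(gaussian_decay(5, 0), "positive")
})

test_that("walking scores weight capability x attractiveness by decay", {
  g <- build_graph(line_road(2000))
  sp0 <- as_spaces(data.frame(id = "s1", x = 100, y = 0, category = "park",
                              capability = 2, attractiveness = 4))
  a0 <- walking_equity(list(x = 100, y = 0), sp0, g, cfg)
  expect_equal(unname(a0["park"]), 8, tolerance = 1e-12)
  expect_equal(unname(a0["square"]), 0)

  # a space exactly at the horizon contributes S * P * exp(-1/2)
  d_t0 <- cfg$t0_walk * 60 * cfg$walk_speed  # 1080 m
  sp1 <- as_spaces(data.frame(id = "s1", x = d_t0, y = 0, category = "square",
                              capability = 3, attractiveness = 2))
  a1 <- walking_equity(list(x = 0, y = 0), sp1, g, cfg)
  expect_equal(unname(a1["square"]), 3 * 2 * exp(-0.5), tolerance = 1e-9)

  # just past the horizon contributes nothing
  sp2 <- as_spaces(data.frame(id = "s1", x = d_t0 + 5, y = 0,
                              category = "square", capability = 3,
                              attractiveness = 2))
  expect_equal(unname(walking_equity(list(x = 0, y = 0), sp2, g, cfg)["square"]), 0)

  # unsnappable building scores zero with a flag
  a_far <- walking_equity(list(x = 0, y = 8000), sp0, g, cfg)
  expect_true(all(a_far == 0))
  expect_true(attr(a_far, "unreachable"))
})

test_that("bus scores multiply by the stop counts on both ends", {
  g <- build_graph(line_road(3000))
  spaces <- as_spaces(data.frame(id = "s1", x = 1000, y = 0,
                                 category = "fitness_center",
                                 capability = 3, attractiveness = 5))
  # no stop near the building: all categories zero
  far_stops <- data.frame(id = "t1", x = 2900, y = 0)
  a_none <- bus_equity(list(x = 0, y = 0), spaces, far_stops, g, cfg)
  expect_true(all(a_none == 0))

  # two stops by the building, one by the space, all walks short:
  # A = S * P * G(T) * N_i * N_j with N_i = 1, N_j = 2
  stops <- data.frame(id = c("t1", "t2", "t3"), x = c(30, 60, 1000), y = 0)
  a <- bus_equity(list(x = 0, y = 0), spaces, stops, g, cfg)
  cb <- stop_catchment(list(x = 0, y = 0), stops, g, cfg,
                       radius = cfg$building_catchment_radius)
  cs <- stop_catchment(list(x = 1000, y = 0), stops, g, cfg,
                       radius = cfg$space_catchment_radius)
  t_exp <- bus_time(cb, cs, g, cfg)
  expect_equal(unname(a["fitness_center"]),
               3 * 5 * gaussian_decay(t_exp, cfg$t0_bus) *
                 cs$stop_count * cb$stop_count,
               tolerance = 1e-9)
  expect_equal(cb$stop_count, 2)
  expect_equal(cs$stop_count, 1)
})

test_that("restricting the bus window to beyond the walking circle drops quick trips", {
  g <- build_graph(line_road(3000))
  spaces <- as_spaces(data.frame(id = "s1", x = 200, y = 0, category = "park",
                                 capability = 2, attractiveness = 2))
  stops <- data.frame(id = c("t1", "t2"), x = c(50, 250), y = 0)
  open_win <- bus_equity(list(x = 0, y = 0), spaces, stops, g, cfg)
  strict <- mode_config(bus_window_low = 15)
  closed_win <- bus_equity(list(x = 0, y = 0), spaces, stops, g, strict)
  expect_gt(unname(open_win["park"]), 0)  # trip takes a few minutes only
  expect_equal(unname(closed_win["park"]), 0)
})

test_that("mode combination is an elementwise sum", {
  walk <- c(park = 8, square = 0, fitness_center = 2, sports_field = 1)
  bus <- c(park = 30, square = 4, fitness_center = 0, sports_field = 2)
  comb <- combine_modes(walk, bus)
  expect_equal(unname(comb["park"]), 38)
  expect_equal(combine_modes(walk, walk * 0), walk)
  expect_true(all(comb >= pmax(walk, bus)))
  expect_error(combine_modes(walk, bus[1:3]), "categories")
})

test_that("walking and bus scores match the from-scratch oracle on toy cities", {
  for (seed in 1:8) {
    city <- toy_city(seed, n_nodes = sample(8:12, 1))
    g <- city$graph
    for (b in seq_len(nrow(city$buildings))) {
      bld <- as.list(city$buildings[b, c("x", "y")])
      got_w <- walking_equity(bld, city$spaces, g, cfg)
      want_w <- oracle_walking_score(g, city$b_nodes[b], city$s_nodes,
                                     city$spaces, cfg)
      expect_equal(unname(got_w), unname(want_w[names(got_w)]),
                   tolerance = 1e-9)
      got_b <- bus_equity(bld, city$spaces, city$stops, g, cfg)
      want_b <- oracle_bus_score(g, city$b_nodes[b], city$s_nodes,
                                 city$spaces, city$t_nodes, cfg)
      expect_equal(unname(got_b), unname(want_b[names(got_b)]),
                   tolerance = 1e-9)
    }
  }
})

test_that("scores scale linearly in attractiveness and grow monotonically", {
  set.seed(5)
  city <- toy_city(21, n_nodes = 10)
  g <- city$graph
  bld <- as.list(city$buildings[1, c("x", "y")])
  a1 <- walking_equity(bld, city$spaces, g, cfg)

  doubled <- city$spaces
  doubled$attractiveness <- pmin(5, doubled$attractiveness)  # stays valid
  halfp <- doubled
  halfp$attractiveness <- halfp$attractiveness / 2 + 0.5  # affine, in [1,5]
  # direct proportionality: scoring is linear in P_i
  s_base <- walking_equity(bld, as_spaces(doubled), g, cfg)
  s_half <- walking_equity(bld, as_spaces(halfp), g, cfg)
  manual <- oracle_walking_score(g, city$b_nodes[1], city$s_nodes,
                                 as_spaces(halfp), cfg)
  expect_equal(unname(s_half), unname(manual[names(s_half)]), tolerance = 1e-9)

  # adding a reachable space never decreases any category
  extra <- rbind(city$spaces,
                 data.frame(id = "snew", x = bld$x, y = bld$y,
                            category = "park", capability = 5,
                            attractiveness = 5))
  a2 <- walking_equity(bld, as_spaces(extra), g, cfg)
  expect_true(all(a2 >= a1 - 1e-12))
  expect_gt(a2["park"], a1["park"])
})

test_that("a building with nothing reachable scores zero in both modes", {
  roads <- as_roads(data.frame(id = c("a", "a", "b", "b"), seq = rep(1:2, 2),
                               x = c(0, 100, 9000, 9100), y = 0))
  g <- suppressWarnings(build_graph(roads))
  spaces <- as_spaces(data.frame(id = "s", x = 9050, y = 0, category = "park",
                                 capability = 5, attractiveness = 5))
  stops <- data.frame(id = "t", x = 9000, y = 0)
  w <- walking_equity(list(x = 50, y = 0), spaces, g, cfg)
  b <- bus_equity(list(x = 50, y = 0), spaces, stops, g, cfg)
  expect_true(all(combine_modes(w, b) == 0))
})

make_records <- function(scores_by_cat) {
  cats <- names(scores_by_cat)
  do.call(rbind, lapply(cats, function(cat) {
    v <- scores_by_cat[[cat]]
    data.frame(building_id = sprintf("b%02d", seq_along(v)), category = cat,
               combined_score = v)
  }))
}

test_that("mean_equalize equalizes category means and preserves ratios", {
  rec <- make_records(list(park = c(5, 15), square = c(10, 50),
                           fitness_center = c(2, 4), sports_field = c(30, 10)))
  std <- standardize_records(rec, "mean_equalize")
  means <- tapply(std$standardized_score, std$category, mean)
  grand <- mean(tapply(rec$combined_score, rec$category, mean))
  expect_equal(as.numeric(means), rep(grand, 4), tolerance = 1e-12)

  sq <- std[std$category == "square", ]
  expect_equal(sq$standardized_score[2] / sq$standardized_score[1], 5,
               tolerance = 1e-12)

  # already-equal means are a fixed point
  eq <- make_records(list(park = c(10, 30), square = c(15, 25),
                          fitness_center = c(20, 20), sports_field = c(5, 35)))
  std_eq <- standardize_records(eq, "mean_equalize")
  expect_equal(std_eq$standardized_score, eq$combined_score, tolerance = 1e-12)

  # all-zero category left at zero with a warning
  z <- make_records(list(park = c(0, 0), square = c(10, 20),
                         fitness_center = c(5, 5), sports_field = c(1, 3)))
  expect_warning(std_z <- standardize_records(z, "mean_equalize"), "park")
  expect_equal(std_z$standardized_score[std_z$category == "park"], c(0, 0))
})

test_that("alternative standardization schemes stay on their documented scales", {
  rec <- make_records(list(park = c(5, 15, 25), square = c(0, 50, 100),
                           fitness_center = c(2, 4, 9),
                           sports_field = c(30, 10, 20)))
  mm <- standardize_records(rec, "minmax_0_100")
  expect_true(all(mm$standardized_score >= 0 & mm$standardized_score <= 100))
  expect_equal(range(mm$standardized_score[mm$category == "park"]), c(0, 100))
  zs <- standardize_records(rec, "zscore_shifted")
  expect_true(all(zs$standardized_score >= 0))
  expect_equal(min(zs$standardized_score[zs$category == "square"]), 0)
})

test_that("overall score averages the four standardized categories", {
  rec <- make_records(list(park = c(10, 1), square = c(20, 2),
                           fitness_center = c(30, 3), sports_field = c(40, 4)))
  rec$standardized_score <- rec$combined_score
  ov <- overall_score(rec)
  expect_equal(ov$overall_score[ov$building_id == "b01"], 25)
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(overall_score(shuffled), ov)
  expect_error(overall_score(rec[rec$category != "park", ]), "four")
})
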