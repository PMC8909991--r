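cfg <- mode_config()

test_that("graph construction merges shared endpoints and censuses components", {
  g <- build_graph(unit_square_roads())
  expect_equal(nrow(g$nodes), 4)
  expect_equal(nrow(g$edges), 4)
  expect_equal(g$edges$length, rep(1, 4))
  expect_equal(g$n_components, 1)

  near <- as_roads(data.frame(id = c("a", "a", "b", "b"), seq = rep(1:2, 2),
                              x = c(0, 100, 100.3, 200), y = c(0, 0, 0, 0)))
  g2 <- build_graph(near, merge_tolerance = 0.5)
  expect_equal(g2$n_components, 1)
  expect_equal(nrow(g2$nodes), 3)

  far <- as_roads(data.frame(id = c("a", "a", "b", "b"), seq = rep(1:2, 2),
                             x = c(0, 100, 5000, 5100), y = c(0, 0, 0, 0)))
  expect_warning(g3 <- build_graph(far), "disconnected")
  expect_equal(g3$n_components, 2)

  expect_error(build_graph(as_roads(data.frame(id = "z", seq = 1:3,
                                               x = c(0, 1, 0), y = c(0, 0, 0))),
                           merge_tolerance = 2),
               "degenerate")
})

test_that("snapping projects onto the nearest edge and flags far points", {
  g <- build_graph(line_road(1000))
  on_edge <- snap(list(x = 250, y = 0), g, cfg)
  expect_equal(on_edge$access_time, 0)
  expect_true(on_edge$snapped)

  perp <- snap(list(x = 500, y = 72), g, cfg)
  expect_equal(perp$offset_m, 72)
  expect_equal(perp$access_time, 1.0)  # 72 m at 1.2 m/s = 60 s
  expect_equal(unname(perp$snapped_point["x"]), 500)

  beyond <- snap(list(x = 500, y = 600), g, cfg)
  expect_false(beyond$snapped)

  past_end <- snap(list(x = 1100, y = 0), g, cfg)
  expect_equal(past_end$offset_m, 100)
  expect_equal(unname(past_end$snapped_point["x"]), 1000)
})

test_that("walking times compose access, network and egress legs", {
  g <- build_graph(line_road(1000))
  # origin and target snap to the same point: only the two access legs remain
  t_same <- walk_times(list(x = 300, y = 36), data.frame(id = "a", x = 300, y = -72),
                       g, cfg, cutoff = 100)
  expect_equal(unname(t_same["a"]), (36 + 72) / 1.2 / 60)

  # beyond-cutoff target omitted; unreachable origin flagged
  t_cut <- walk_times(list(x = 0, y = 0),
                      data.frame(id = c("near", "far"), x = c(100, 1000),
                                 y = c(0, 0)), g, cfg, cutoff = 5)
  expect_named(t_cut, "near")
  t_unr <- walk_times(list(x = 0, y = 5000), data.frame(id = "a", x = 100, y = 0),
                      g, cfg)
  expect_length(t_unr, 0)
  expect_true(attr(t_unr, "unreachable"))
})

test_that("network times match the exhaustive simple-path oracle on random graphs", {
  set.seed(42)
  for (rep in 1:20) {
    net <- random_road_network(sample(5:10, 1))
    graph <- suppressWarnings(build_graph(net$roads))
    nm <- node_names_at(graph, net$nodes)
    oracle <- oracle_all_pairs(graph)
    origin_i <- sample(nrow(net$nodes), 1)
    targets <- data.frame(id = graph$nodes$name, x = graph$nodes$x,
                          y = graph$nodes$y)
    got <- walk_times(list(x = net$nodes$x[origin_i], y = net$nodes$y[origin_i]),
                      targets, graph, cfg, cutoff = Inf)
    want <- oracle[nm[origin_i], names(got)] / cfg$walk_speed / 60
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("network distance never beats the straight line", {
  set.seed(7)
  for (rep in 1:10) {
    net <- random_road_network(8)
    graph <- suppressWarnings(build_graph(net$roads))
    targets <- data.frame(id = graph$nodes$name, x = graph$nodes$x,
                          y = graph$nodes$y)
    o <- list(x = net$nodes$x[1], y = net$nodes$y[1])
    got <- walk_times(o, targets, graph, cfg, cutoff = Inf)
    eu <- sqrt((targets$x - o$x)^2 + (targets$y - o$y)^2)
    names(eu) <- targets$id
    expect_true(all(got >= eu[names(got)] / cfg$walk_speed / 60 - 1e-9))
  }
})

test_that("cutoffs are monotone and extra edges never slow travel", {
  set.seed(13)
  for (rep in 1:10) {
    net <- random_road_network(9, extra_edges = 1)
    graph <- suppressWarnings(build_graph(net$roads))
    targets <- data.frame(id = graph$nodes$name, x = graph$nodes$x,
                          y = graph$nodes$y)
    o <- list(x = net$nodes$x[2], y = net$nodes$y[2])
    t_small <- walk_times(o, targets, graph, cfg, cutoff = 2)
    t_big <- walk_times(o, targets, graph, cfg, cutoff = 6)
    expect_true(all(names(t_small) %in% names(t_big)))

    # add a shortcut edge between two random nodes: no time may increase
    long <- rbind(
      do.call(rbind, lapply(seq_len(nrow(net$roads)), function(k) {
        m <- net$roads$geometry[[k]]
        data.frame(id = net$roads$id[k], seq = seq_len(nrow(m)),
                   x = m[, 1], y = m[, 2])
      })),
      data.frame(id = "shortcut", seq = 1:2,
                 x = net$nodes$x[c(1, nrow(net$nodes))],
                 y = net$nodes$y[c(1, nrow(net$nodes))]))
    graph2 <- suppressWarnings(build_graph(as_roads(long)))
    t_before <- walk_times(o, targets, graph, cfg, cutoff = Inf)
    t_after <- walk_times(o, targets, graph2, cfg, cutoff = Inf)
    expect_true(all(t_after[names(t_before)] <= t_before + 1e-9))
  }
})

test_that("stop catchments count in-range stops and average walk times", {
  g <- build_graph(line_road(2000))
  stops3 <- data.frame(id = c("t1", "t2", "t3"), x = c(120, 240, 360), y = 0)
  none <- stop_catchment(list(x = 1900, y = 0), stops3, g, cfg, radius = 400)
  expect_equal(none$stop_count, 0)
  expect_true(is.na(none$mean_walk_time))

  one <- stop_catchment(list(x = 0, y = 0),
                        data.frame(id = "t1", x = 400, y = 0), g, cfg,
                        radius = 400)
  expect_equal(one$stop_count, 1)
  expect_equal(one$mean_walk_time, 400 / 1.2 / 60, tolerance = 1e-9)

  three <- stop_catchment(list(x = 0, y = 0), stops3, g, cfg, radius = 400)
  expect_equal(three$stop_count, 3)
  expect_equal(three$mean_walk_time, mean(c(120, 240, 360)) / 1.2 / 60,
               tolerance = 1e-9)

  # enlarged radius never loses stops
  for (r in c(100, 200, 300, 500)) {
    small <- stop_catchment(list(x = 0, y = 0), stops3, g, cfg, radius = r)
    big <- stop_catchment(list(x = 0, y = 0), stops3, g, cfg, radius = r + 150)
    expect_gte(big$stop_count, small$stop_count)
  }
})

test_that("bus times compose the catchment walks with the best stop pair", {
  g <- build_graph(line_road(6000))
  # building and space share one stop: p = 0, T = w_j + w_i
  shared <- data.frame(id = "t1", x = 100, y = 0)
  cb <- stop_catchment(list(x = 0, y = 0), shared, g, cfg, radius = 600)
  cs <- stop_catchment(list(x = 300, y = 0), shared, g, cfg, radius = 400)
  expect_equal(bus_time(cb, cs, g, cfg),
               cb$mean_walk_time + cs$mean_walk_time, tolerance = 1e-9)

  # single pair 5 km apart at 10 km/h: in-vehicle leg alone is 30 min
  stops <- data.frame(id = c("a", "b"), x = c(100, 5100), y = 0)
  cb2 <- stop_catchment(list(x = 0, y = 0), stops, g, cfg, radius = 600)
  cs2 <- stop_catchment(list(x = 5200, y = 0), stops, g, cfg, radius = 400)
  t2 <- bus_time(cb2, cs2, g, cfg)
  expect_equal(t2 - cb2$mean_walk_time - cs2$mean_walk_time, 30,
               tolerance = 1e-9)
  expect_gt(t2, cfg$t0_bus)  # unreachable under the 30-min horizon

  # empty catchment on either side is unreachable
  empty <- stop_catchment(list(x = 0, y = 0),
                          data.frame(id = "z", x = 5900, y = 0), g, cfg,
                          radius = 400)
  expect_equal(bus_time(empty, cs2, g, cfg), Inf)
})

test_that("the in-vehicle leg equals the brute-force minimum over stop pairs", {
  set.seed(31)
  for (rep in 1:10) {
    city <- toy_city(seed = 100 + rep, n_nodes = 10, n_stops = 4)
    g <- city$graph
    cb <- stop_catchment(as.list(city$buildings[1, c("x", "y")]),
                         city$stops[1:2, ], g, cfg, radius = 1e6)
    cs <- stop_catchment(as.list(city$spaces[1, c("x", "y")]),
                         city$stops[3:4, ], g, cfg, radius = 1e6)
    got <- bus_time(cb, cs, g, cfg)
    p_oracle <- Inf
    for (a in city$t_nodes[1:2]) {
      for (b in city$t_nodes[3:4]) {
        d <- if (identical(a, b)) 0 else oracle_net_meters(g, a, b)
        p_oracle <- min(p_oracle, d)
      }
    }
    want <- cb$mean_walk_time + p_oracle / cfg$bus_speed / 60 + cs$mean_walk_time
    expect_equal(got, want, tolerance = 1e-9)
  }
})
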