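# Fixture builders: small random road networks and toy cities, generated in
# code under explicit seeds.

# n random node locations with pairwise separation > 2 m (so the 0.5 m
# vertex merge never fuses distinct nodes)
scatter_nodes <- function(n, span = 300) {
  repeat {
    x <- runif(n, 0, span); y <- runif(n, 0, span)
    if (n < 2 || min(dist(cbind(x, y))) > 2) return(data.frame(x = x, y = y))
  }
}

# connected random graph as a roads layer: random spanning tree plus a few
# extra edges; sparse so exhaustive path enumeration stays cheap
random_road_network <- function(n_nodes, extra_edges = 2, span = 300) {
  pts <- scatter_nodes(n_nodes, span)
  edges <- cbind(2:n_nodes, vapply(2:n_nodes, function(i) sample(i - 1, 1), 0L))
  if (extra_edges > 0) {
    all_pairs <- t(combn(n_nodes, 2))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    cand <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% key), ,
                      drop = FALSE]
    if (nrow(cand) > 0) {
      pick <- sample(nrow(cand), min(extra_edges, nrow(cand)))
      edges <- rbind(edges, cand[pick, , drop = FALSE])
    }
  }
  long <- do.call(rbind, lapply(seq_len(nrow(edges)), function(k) {
    data.frame(id = sprintf("r%03d", k), seq = 1:2,
               x = pts$x[edges[k, ]], y = pts$y[edges[k, ]])
  }))
  list(roads = as_roads(long), nodes = pts)
}

# map fixture node coordinates to the names build_graph assigned them
node_names_at <- function(graph, pts) {
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (graph$nodes$x - pts$x[i])^2 + (graph$nodes$y - pts$y[i])^2
    graph$nodes$name[which.min(d2)]
  }, "")
}

# toy city with buildings, spaces and stops placed exactly on graph nodes,
# sized for exhaustive oracle checking
toy_city <- function(seed, n_nodes = 12, n_spaces = 5, n_stops = 4,
                     n_buildings = 2) {
  set.seed(seed)
  net <- random_road_network(n_nodes, extra_edges = sample(0:3, 1))
  graph <- suppressWarnings(build_graph(net$roads))
  names_all <- node_names_at(graph, net$nodes)
  picks <- sample(n_nodes, n_buildings + n_spaces + n_stops, replace = TRUE)
  bi <- picks[seq_len(n_buildings)]
  si <- picks[n_buildings + seq_len(n_spaces)]
  ti <- picks[n_buildings + n_spaces + seq_len(n_stops)]
  cats <- c("park", "square", "fitness_center", "sports_field")
  spaces <- data.frame(
    id = sprintf("s%02d", seq_len(n_spaces)),
    x = net$nodes$x[si], y = net$nodes$y[si],
    category = sample(cats, n_spaces, replace = TRUE),
    capability = sample(1:5, n_spaces, replace = TRUE),
    attractiveness = round(runif(n_spaces, 1, 5), 2))
  list(graph = graph,
       buildings = data.frame(id = sprintf("b%02d", seq_len(n_buildings)),
                              x = net$nodes$x[bi], y = net$nodes$y[bi]),
       b_nodes = names_all[bi],
       spaces = as_spaces(spaces),
       s_nodes = names_all[si],
       stops = data.frame(id = sprintf("t%02d", seq_len(n_stops)),
                          x = net$nodes$x[ti], y = net$nodes$y[ti]),
       t_nodes = names_all[ti])
}

# straight east-west road through the origin, handy for arithmetic cases
line_road <- function(length_m = 1000) {
  as_roads(data.frame(id = "r1", seq = 1:2, x = c(0, length_m), y = c(0, 0)))
}

# back-convert a roads layer to the long vertex form as_roads() accepts
roads_long_form <- function(roads) {
  do.call(rbind, lapply(seq_len(nrow(roads)), function(k) {
    m <- roads$geometry[[k]]
    data.frame(id = roads$id[k], seq = seq_len(nrow(m)),
               x = m[, 1], y = m[, 2])
  }))
}

unit_square_roads <- function() {
  as_roads(data.frame(id = rep(c("e1", "e2", "e3", "e4"), each = 2),
                      seq = rep(1:2, 4),
                      x = c(0, 1, 1, 1, 1, 0, 0, 0),
                      y = c(0, 0, 0, 1, 1, 1, 1, 0)))
}
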