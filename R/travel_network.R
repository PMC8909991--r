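#' Build a routable road graph from road centerlines
#'
#' Polyline vertices become graph nodes (merged when closer than
#' `merge_tolerance`), and each consecutive vertex pair becomes an undirected
#' edge weighted by its Euclidean length in meters. One-way restrictions are
#' ignored: pedestrians are direction-agnostic and the bus model is too
#' coarse to use them. A connected-component census is run and a warning is
#' emitted when the network is fragmented, since travel between components
#' is impossible.
#'
#' @param roads A validated roads layer (see [as_roads()]), or a long-form
#'   data frame coercible by [as_roads()].
#' @param merge_tolerance Vertices closer than this many meters are merged
#'   into one node. Default 0.5.
#' @return A `travel_graph`: nodes with coordinates, straight edge segments
#'   with lengths, and the underlying weighted [igraph][igraph::graph] used
#'   for shortest-path search.
#' @examples
#' roads <- data.frame(id = "r1", seq = 1:2, x = c(0, 100), y = c(0, 0))
#' g <- build_graph(as_roads(roads))
#' g$n_components
#' @export
build_graph <- function(roads, merge_tolerance = 0.5) {
  if (!("geometry" %in% names(roads))) roads <- as_roads(roads)
  if (nrow(roads) < 1) stop("need at least one road segment")

  # incremental vertex merge: each polyline vertex is matched to the first
  # existing node within tolerance, else becomes a new node
  nx <- numeric(0); ny <- numeric(0)
  node_of_vertex <- function(px, py) {
    if (length(nx)) {
      d2 <- (nx - px)^2 + (ny - py)^2
      j <- which(d2 <= merge_tolerance^2)
      if (length(j)) return(j[1])
    }
    nx[length(nx) + 1] <<- px
    ny[length(ny) + 1] <<- py
    length(nx)
  }

  from <- integer(0); to <- integer(0); road_id <- character(0)
  for (k in seq_len(nrow(roads))) {
    m <- roads$geometry[[k]]
    idx <- vapply(seq_len(nrow(m)), function(i) node_of_vertex(m[i, 1], m[i, 2]), 0L)
    a <- idx[-length(idx)]; b <- idx[-1]
    ok <- a != b
    from <- c(from, a[ok]); to <- c(to, b[ok])
    road_id <- c(road_id, rep(roads$id[k], sum(ok)))
  }
  if (!length(from)) stop("all road segments are degenerate after vertex merging")

  nodes <- data.frame(name = paste0("n", seq_along(nx)), x = nx, y = ny,
                      stringsAsFactors = FALSE)
  len <- sqrt((nx[from] - nx[to])^2 + (ny[from] - ny[to])^2)
  edges <- data.frame(edge_id = seq_along(from), road_id = road_id,
                      from = nodes$name[from], to = nodes$name[to],
                      length = len, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "length", "edge_id")],
    directed = FALSE, vertices = nodes)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warning(sprintf("road network has %d disconnected components", comp$no))
  }
  structure(list(nodes = nodes, edges = edges, graph = g,
                 merge_tolerance = merge_tolerance,
                 n_components = comp$no),
            class = "travel_graph")
}

#' @export
print.travel_graph <- function(x, ...) {
  cat(sprintf("<travel_graph> %d nodes, %d edges, %d component%s\n",
              nrow(x$nodes), nrow(x$edges), x$n_components,
              if (x$n_components == 1) "" else "s"))
  invisible(x)
}

# Nearest point on any edge segment for each row of `points` (id, x, y).
# Ties in offset are broken by the lowest edge id (edges are stored in
# edge-id order and which.min keeps the first minimum).
snap_points <- function(points, graph, config = mode_config()) {
  e <- graph$edges
  ni <- match(e$from, graph$nodes$name)
  nj <- match(e$to, graph$nodes$name)
  ax <- graph$nodes$x[ni]; ay <- graph$nodes$y[ni]
  dx <- graph$nodes$x[nj] - ax; dy <- graph$nodes$y[nj] - ay
  len2 <- dx^2 + dy^2

  n <- nrow(points)
  out <- data.frame(id = as.character(points$id), x = points$x, y = points$y,
                    edge_index = rep(NA_integer_, n), t = rep(NA_real_, n),
                    snap_x = rep(NA_real_, n), snap_y = rep(NA_real_, n),
                    offset_m = rep(NA_real_, n), snapped = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    px <- points$x[i]; py <- points$y[i]
    tt <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    fx <- ax + tt * dx; fy <- ay + tt * dy
    d2 <- (px - fx)^2 + (py - fy)^2
    j <- which.min(d2)
    out$edge_index[i] <- j
    out$t[i] <- tt[j]
    out$snap_x[i] <- fx[j]
    out$snap_y[i] <- fy[j]
    out$offset_m[i] <- sqrt(d2[j])
  }
  out$snapped <- out$offset_m <= config$max_snap_distance
  out$access_min <- walk_minutes(out$offset_m, config)
  out
}

#' Snap a point onto the road network
#'
#' Finds the nearest location on any road edge (perpendicular projection
#' onto the segment, or the nearest endpoint) and reports the off-network
#' access leg: its length and the minutes needed to walk it. Points farther
#' than `max_snap_distance` from every edge are flagged unreachable and are
#' excluded from scoring downstream.
#'
#' @param point A list or one-row data frame with `x` and `y` (meters).
#' @param graph A [build_graph()] result.
#' @param config A [mode_config()].
#' @return A list: `source_point`, `snapped_point`, `offset_m`,
#'   `access_time` (minutes), `host_edge` (edge id), `snapped` (logical;
#'   `FALSE` means unreachable from the network).
#' @examples
#' g <- build_graph(as_roads(data.frame(id = "r", seq = 1:2,
#'                                      x = c(0, 100), y = c(0, 0))))
#' snap(list(x = 50, y = 72), g)$access_time  # 72 m at 1.2 m/s = 1 min
#' @export
snap <- function(point, graph, config = mode_config()) {
  s <- snap_points(data.frame(id = "p", x = point$x, y = point$y), graph, config)
  list(source_point = c(x = s$x, y = s$y),
       snapped_point = c(x = s$snap_x, y = s$snap_y),
       offset_m = s$offset_m,
       access_time = s$access_min,
       host_edge = graph$edges$edge_id[s$edge_index],
       snapped = s$snapped)
}

# Insert snapped points as nodes splitting their host edges, so network
# distances start exactly at the snap locations rather than at the nearest
# pre-existing vertex. Points whose snap location coincides (same edge and
# parameter within 1e-9) share one node; snaps landing on an edge endpoint
# reuse that endpoint.
augment_graph <- function(graph, snaps) {
  e <- graph$edges
  node_of <- setNames(rep(NA_character_, nrow(snaps)), snaps$id)
  splits <- list()  # per edge index: named numeric of t values

  for (i in seq_len(nrow(snaps))) {
    if (!snaps$snapped[i]) next
    j <- snaps$edge_index[i]
    t <- snaps$t[i]
    L <- e$length[j]
    if (t * L < 1e-9) {
      node_of[i] <- e$from[j]
    } else if ((1 - t) * L < 1e-9) {
      node_of[i] <- e$to[j]
    } else {
      key <- as.character(j)
      ts <- splits[[key]]
      hit <- if (is.null(ts)) integer(0) else which(abs(ts - t) * L < 1e-9)
      if (length(hit)) {
        node_of[i] <- names(ts)[hit[1]]
      } else {
        nm <- sprintf("s%d_%d", j, length(ts) + 1L)
        splits[[key]] <- c(ts, setNames(t, nm))
        node_of[i] <- nm
      }
    }
  }

  if (!length(splits)) {
    return(list(graph = graph$graph, node_of = node_of))
  }

  split_idx <- as.integer(names(splits))
  keep <- e[-split_idx, c("from", "to", "length"), drop = FALSE]
  extra <- list()
  new_nodes <- character(0)
  for (k in seq_along(splits)) {
    j <- split_idx[k]
    ts <- sort(splits[[k]])
    chain <- c(e$from[j], names(ts), e$to[j])
    tt <- c(0, unname(ts), 1)
    extra[[k]] <- data.frame(from = chain[-length(chain)], to = chain[-1],
                             length = diff(tt) * e$length[j],
                             stringsAsFactors = FALSE)
    new_nodes <- c(new_nodes, names(ts))
  }
  edges2 <- rbind(keep, do.call(rbind, extra))
  vertices <- data.frame(name = c(graph$nodes$name, new_nodes),
                         stringsAsFactors = FALSE)
  g2 <- igraph::graph_from_data_frame(edges2, directed = FALSE,
                                      vertices = vertices)
  list(graph = g2, node_of = node_of)
}

# Snap several point groups once, augment the graph once, and expose
# network shortest-path distances (meters, snap node to snap node) between
# any two groups. Offsets (Euclidean access legs) are kept per group.
prepare_routing <- function(graph, groups, config = mode_config()) {
  snaps <- lapply(names(groups), function(nm) {
    pts <- groups[[nm]]
    s <- snap_points(pts[, c("id", "x", "y")], graph, config)
    s$group <- rep(nm, nrow(s))
    s
  })
  all_snaps <- do.call(rbind, snaps)
  aug <- augment_graph(graph, all_snaps)
  idx <- split(seq_len(nrow(all_snaps)), all_snaps$group)
  structure(list(graph = aug$graph, snaps = all_snaps,
                 node_of = aug$node_of, idx = idx, config = config),
            class = "routing_prep")
}

# net-only shortest-path meters between two prepared groups; Inf where a
# point is unsnapped or disconnected
net_meters <- function(prep, from_group, to_group) {
  si <- prep$snaps[prep$idx[[from_group]], , drop = FALSE]
  sj <- prep$snaps[prep$idx[[to_group]], , drop = FALSE]
  m <- matrix(Inf, nrow(si), nrow(sj), dimnames = list(si$id, sj$id))
  oki <- si$snapped; okj <- sj$snapped
  if (any(oki) && any(okj)) {
    ni <- prep$node_of[prep$idx[[from_group]]][oki]
    nj <- prep$node_of[prep$idx[[to_group]]][okj]
    d <- igraph::distances(prep$graph, v = unique(ni), to = unique(nj),
                           weights = igraph::E(prep$graph)$length)
    m[oki, okj] <- d[ni, nj, drop = FALSE]
  }
  m
}

# door-to-door walking meters: access leg + network path + egress leg
walk_meters <- function(prep, from_group, to_group) {
  si <- prep$snaps[prep$idx[[from_group]], , drop = FALSE]
  sj <- prep$snaps[prep$idx[[to_group]], , drop = FALSE]
  net_meters(prep, from_group, to_group) +
    outer(si$offset_m, sj$offset_m, "+")
}

offsets_of <- function(prep, group) {
  s <- prep$snaps[prep$idx[[group]], , drop = FALSE]
  setNames(s$offset_m, s$id)
}

snapped_of <- function(prep, group) {
  s <- prep$snaps[prep$idx[[group]], , drop = FALSE]
  setNames(s$snapped, s$id)
}

#' Walking travel times from one origin to many targets
#'
#' Door-to-door time: the Euclidean access leg from the origin to its snap
#' point on the network, the shortest network path, and the egress leg to
#' the target, all at walking speed. Targets beyond the cutoff (or not
#' connected) are omitted from the result.
#'
#' @param origin A list or one-row data frame with `x`, `y`.
#' @param targets A data frame with `id`, `x`, `y`.
#' @param graph A [build_graph()] result.
#' @param config A [mode_config()].
#' @param cutoff Maximum minutes; defaults to `config$t0_walk`.
#' @return A named numeric vector of minutes, one entry per reachable
#'   target. If the origin cannot be snapped the vector is empty and has
#'   `attr(, "unreachable") = TRUE`.
#' @export
walk_times <- function(origin, targets, graph, config = mode_config(),
                       cutoff = config$t0_walk) {
  prep <- prepare_routing(
    graph,
    list(origin = data.frame(id = "origin", x = origin$x, y = origin$y),
         targets = targets[, c("id", "x", "y")]),
    config)
  if (!snapped_of(prep, "origin")[["origin"]]) {
    out <- numeric(0)
    attr(out, "unreachable") <- TRUE
    return(out)
  }
  m <- walk_meters(prep, "origin", "targets")
  meters <- setNames(m[1, ], colnames(m))
  mins <- walk_minutes(meters, config)
  mins <- mins[is.finite(mins) & mins <= cutoff + TIME_EPS_MIN]
  mins
}

#' Bus stops within walking range of a point
#'
#' Counts the bus stops whose door-to-door walking distance from `center`
#' is at most `radius` meters (measured along the road network by default;
#' set `catchment_metric = "euclidean"` in the config for straight-line
#' distance) and averages the walking time to them. This is the N / w pair
#' entering the bus-mode score: stop count around a facility (400 m) or a
#' building (600 m) and the mean walk time to those stops.
#'
#' @param center A list or one-row data frame with `x`, `y`.
#' @param stops A bus-stop layer (`id`, `x`, `y`).
#' @param graph A [build_graph()] result.
#' @param config A [mode_config()].
#' @param radius Catchment radius in meters.
#' @return A list: `stop_count`, `mean_walk_time` (minutes; `NA` when no
#'   stop is in range), `stop_ids`, `walk_minutes` (named per stop), and
#'   the in-range `stops` subset.
#' @export
stop_catchment <- function(center, stops, graph, config = mode_config(),
                           radius) {
  if (config$catchment_metric == "euclidean") {
    meters <- sqrt((stops$x - center$x)^2 + (stops$y - center$y)^2)
    names(meters) <- stops$id
  } else {
    prep <- prepare_routing(
      graph,
      list(center = data.frame(id = "center", x = center$x, y = center$y),
           stops = stops[, c("id", "x", "y")]),
      config)
    m <- walk_meters(prep, "center", "stops")
    meters <- setNames(m[1, ], colnames(m))
  }
  inside <- is.finite(meters) & meters <= radius + RADIUS_EPS_M
  mins <- walk_minutes(meters[inside], config)
  list(stop_count = sum(inside),
       mean_walk_time = if (any(inside)) mean(mins) else NA_real_,
       stop_ids = names(meters)[inside],
       walk_minutes = mins,
       stops = stops[stops$id %in% names(meters)[inside], , drop = FALSE])
}

#' Bus travel time between a building and a sports space
#'
#' Composes the three legs of a bus trip: the mean walk from the building
#' to its in-range stops (`w_j`), the best in-vehicle connection between
#' any stop in the building's catchment and any stop in the space's
#' catchment (`p_ij`, shortest network path at bus speed), and the mean
#' walk from the space's stops to the space (`w_i`). The walking ends use
#' catchment averages; the in-vehicle leg takes the minimum over all stop
#' pairs, i.e. the traveler boards the best connection.
#'
#' @param catchment_b The building's [stop_catchment()].
#' @param catchment_s The space's [stop_catchment()].
#' @param graph A [build_graph()] result.
#' @param config A [mode_config()].
#' @return Total minutes, or `Inf` when either catchment is empty or no
#'   stop pair is connected. Callers treat times beyond `config$t0_bus` as
#'   unreachable.
#' @export
bus_time <- function(catchment_b, catchment_s, graph, config = mode_config()) {
  if (catchment_b$stop_count == 0 || catchment_s$stop_count == 0) return(Inf)
  prep <- prepare_routing(
    graph,
    list(b = catchment_b$stops[, c("id", "x", "y")],
         s = catchment_s$stops[, c("id", "x", "y")]),
    config)
  p_m <- min(net_meters(prep, "b", "s"))
  if (!is.finite(p_m)) return(Inf)
  catchment_b$mean_walk_time + bus_minutes(p_m, config) +
    catchment_s$mean_walk_time
}
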