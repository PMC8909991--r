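# Independent shortest-path oracle: exhaustive depth-first enumeration of
# all simple paths over a travel_graph's edge list. Deliberately avoids any
# shortest-path routine; distances are accumulated edge by edge from the
# source so floating-point association matches a sequential traversal.

oracle_net_meters <- function(graph, from_name, to_name) {
  e <- graph$edges
  nbr <- list()
  for (k in seq_len(nrow(e))) {
    nbr[[e$from[k]]] <- rbind(nbr[[e$from[k]]],
                              data.frame(to = e$to[k], w = e$length[k]))
    nbr[[e$to[k]]] <- rbind(nbr[[e$to[k]]],
                            data.frame(to = e$from[k], w = e$length[k]))
  }
  best <- Inf
  visit <- function(node, dist, seen) {
    if (identical(node, to_name)) {
      if (dist < best) best <<- dist
      return(invisible())
    }
    nb <- nbr[[node]]
    if (is.null(nb)) return(invisible())
    for (k in seq_len(nrow(nb))) {
      v <- nb$to[k]
      if (v %in% seen) next
      visit(v, dist + nb$w[k], c(seen, v))
    }
  }
  visit(from_name, 0, from_name)
  best
}

# single-source oracle: walk every simple path once, keeping the best
# distance seen at each node
oracle_dists_from <- function(graph, from_name) {
  e <- graph$edges
  nm <- graph$nodes$name
  nbr <- setNames(vector("list", length(nm)), nm)
  for (k in seq_len(nrow(e))) {
    nbr[[e$from[k]]] <- rbind(nbr[[e$from[k]]],
                              data.frame(to = e$to[k], w = e$length[k]))
    nbr[[e$to[k]]] <- rbind(nbr[[e$to[k]]],
                            data.frame(to = e$from[k], w = e$length[k]))
  }
  best <- setNames(rep(Inf, length(nm)), nm)
  best[from_name] <- 0
  visit <- function(node, dist, seen) {
    nb <- nbr[[node]]
    if (is.null(nb)) return(invisible())
    for (k in seq_len(nrow(nb))) {
      v <- nb$to[k]
      if (v %in% seen) next
      nd <- dist + nb$w[k]
      if (nd < best[[v]]) best[[v]] <<- nd
      visit(v, nd, c(seen, v))
    }
  }
  visit(from_name, 0, from_name)
  best
}

# all-pairs oracle distance matrix over the graph's own nodes
oracle_all_pairs <- function(graph) {
  nm <- graph$nodes$name
  t(vapply(nm, function(a) oracle_dists_from(graph, a), setNames(numeric(length(nm)), nm)))
}

# From-scratch walking-mode score for a building placed exactly at a graph
# node: decay-weighted capability x attractiveness sum over spaces (also at
# nodes) within the walking horizon.
oracle_walking_score <- function(graph, b_node, space_nodes, spaces, config) {
  cats <- c("park", "square", "fitness_center", "sports_field")
  out <- setNames(numeric(4), cats)
  for (i in seq_len(nrow(spaces))) {
    t_min <- oracle_net_meters(graph, b_node, space_nodes[i]) /
      config$walk_speed / 60
    if (is.finite(t_min) && t_min <= config$t0_walk) {
      out[spaces$category[i]] <- out[spaces$category[i]] +
        spaces$capability[i] * spaces$attractiveness[i] *
        exp(-0.5 * (t_min / config$t0_walk)^2)
    }
  }
  out
}

# From-scratch bus-mode score for a building at a node: stop catchments by
# enumerated walking distance, best enumerated stop-pair connection, then
# the decay- and stop-count-weighted sum.
oracle_bus_score <- function(graph, b_node, space_nodes, spaces, stop_nodes,
                             config) {
  cats <- c("park", "square", "fitness_center", "sports_field")
  out <- setNames(numeric(4), cats)
  walk_m <- function(a, b) oracle_net_meters(graph, a, b)

  b_d <- vapply(stop_nodes, function(s) walk_m(b_node, s), 0)
  b_in <- is.finite(b_d) & b_d <= config$building_catchment_radius
  n_j <- sum(b_in)
  if (n_j == 0) return(out)
  w_j <- mean(b_d[b_in] / config$walk_speed / 60)

  for (i in seq_len(nrow(spaces))) {
    s_d <- vapply(stop_nodes, function(s) walk_m(space_nodes[i], s), 0)
    s_in <- is.finite(s_d) & s_d <= config$space_catchment_radius
    n_i <- sum(s_in)
    if (n_i == 0) next
    w_i <- mean(s_d[s_in] / config$walk_speed / 60)
    p <- Inf
    for (a in stop_nodes[b_in]) {
      for (b in stop_nodes[s_in]) {
        d <- if (identical(a, b)) 0 else walk_m(a, b)
        if (d < p) p <- d
      }
    }
    if (!is.finite(p)) next
    t_total <- w_j + p / config$bus_speed / 60 + w_i
    if (t_total <= config$t0_bus && t_total >= config$bus_window_low) {
      out[spaces$category[i]] <- out[spaces$category[i]] +
        spaces$capability[i] * spaces$attractiveness[i] *
        exp(-0.5 * (t_total / config$t0_bus)^2) * n_i * n_j
    }
  }
  out
}
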