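#' Synthetic-city configuration
#'
#' Parameters of the seeded urban-form generator. The generator emulates
#' the statistical structure the equity analysis assumes in real cities: a
#' connected, slightly irregular street grid; residential buildings whose
#' density decays from the center outward; four categories of sports
#' facilities placed as a mixture of center-clustered and uniform points
#' with discrete 1-5 capability grades and continuous 1-5 attractiveness
#' scores; and bus stops spaced along network routes between peripheral
#' nodes.
#'
#' @param seed Integer master seed. Per-layer sub-seeds are derived from it
#'   so that, e.g., changing the number of buildings does not perturb
#'   facility placement.
#' @param extent Side of the square study area in meters. Default 2000.
#' @param grid_pitch Road spacing in meters. Default 200.
#' @param jitter Fraction of the pitch by which grid nodes are perturbed
#'   (0 = perfect grid). Default 0.15.
#' @param n_buildings Number of residential buildings. Default 400.
#' @param building_gradient Radial density gradient; the default 0 spreads
#'   residential buildings uniformly over the study area (facilities, not
#'   homes, carry the central concentration); larger values concentrate
#'   buildings toward the center as in strongly monocentric cities.
#' @param facility_counts Named integer vector of facility counts per
#'   category. Default 8 parks, 8 squares, 12 fitness centers, 12 sports
#'   fields (40 facilities).
#' @param facility_clustering Per-category probability in [0, 1] that a
#'   facility is drawn from the center-clustered component rather than
#'   uniformly; a scalar is recycled. Default 0.5.
#' @param grade_distribution Probabilities of capability grades 1..5.
#'   Default `c(0.30, 0.25, 0.20, 0.15, 0.10)` (small facilities outnumber
#'   flagship ones).
#' @param attractiveness_mean,attractiveness_sd Location and scale of the
#'   normal distribution, truncated to [1, 5], from which attractiveness
#'   scores are drawn. Defaults 3.5 and 0.8, mimicking review-platform
#'   score distributions.
#' @param n_bus_routes Number of bus routes. Default 2.
#' @param stop_spacing Distance between consecutive stops along a route, in
#'   meters. Default 400.
#' @return A `synthetic_city_config` list.
#' @export
synthetic_city_config <- function(seed = 1L,
                                  extent = 2000,
                                  grid_pitch = 200,
                                  jitter = 0.15,
                                  n_buildings = 400,
                                  building_gradient = 0,
                                  facility_counts = c(park = 8, square = 8,
                                                      fitness_center = 12,
                                                      sports_field = 12),
                                  facility_clustering = 0.5,
                                  grade_distribution = c(0.30, 0.25, 0.20,
                                                         0.15, 0.10),
                                  attractiveness_mean = 3.5,
                                  attractiveness_sd = 0.8,
                                  n_bus_routes = 2,
                                  stop_spacing = 400) {
  stopifnot(length(seed) == 1, is.finite(seed),
            extent > 0, grid_pitch > 0, jitter >= 0,
            n_buildings >= 1, building_gradient >= 0,
            n_bus_routes >= 0, stop_spacing > 0,
            attractiveness_sd > 0,
            attractiveness_mean >= 1, attractiveness_mean <= 5)
  if (grid_pitch > extent) stop("grid_pitch must not exceed the extent")
  if (!setequal(names(facility_counts), SPACE_CATEGORIES)) {
    stop("facility_counts must be named with the four categories")
  }
  facility_counts <- facility_counts[SPACE_CATEGORIES]
  if (all(facility_counts == 0)) stop("at least one facility category must be non-empty")
  if (length(facility_clustering) == 1) {
    facility_clustering <- setNames(rep(facility_clustering, 4), SPACE_CATEGORIES)
  }
  facility_clustering <- facility_clustering[SPACE_CATEGORIES]
  stopifnot(all(facility_clustering >= 0), all(facility_clustering <= 1))
  if (length(grade_distribution) != 5 ||
      abs(sum(grade_distribution) - 1) > 1e-9 || any(grade_distribution < 0)) {
    stop("grade_distribution must be 5 non-negative probabilities summing to 1")
  }
  structure(list(seed = as.integer(seed), extent = extent,
                 grid_pitch = grid_pitch, jitter = jitter,
                 n_buildings = n_buildings,
                 building_gradient = building_gradient,
                 facility_counts = facility_counts,
                 facility_clustering = facility_clustering,
                 grade_distribution = grade_distribution,
                 attractiveness_mean = attractiveness_mean,
                 attractiveness_sd = attractiveness_sd,
                 n_bus_routes = n_bus_routes,
                 stop_spacing = stop_spacing),
            class = "synthetic_city_config")
}

# evaluate `code` under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

# derived per-layer sub-seed, kept inside 32-bit integer range
layer_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1000003) %% 2147483647)
}

#' Generate the synthetic road network
#'
#' A square grid of streets at `grid_pitch` spacing spans the extent; node
#' positions are perturbed by up to `jitter * grid_pitch / 2` per axis to
#' break the perfect regularity of the grid while preserving its topology,
#' so the network is connected by construction. The spanning check is
#' still enforced: should a perturbation ever disconnect the graph, the
#' nearest node pair across components is re-linked.
#'
#' @param config A [synthetic_city_config()].
#' @return A validated roads layer (see [as_roads()]).
#' @export
generate_roads <- function(config) {
  ticks <- seq(0, config$extent, by = config$grid_pitch)
  n <- length(ticks)
  if (n < 2) stop("grid_pitch must not exceed the extent")
  with_seed(layer_seed(config$seed, 1), {
    gx <- matrix(rep(ticks, each = n), n, n)   # column index -> x
    gy <- matrix(rep(ticks, times = n), n, n)  # row index -> y
    if (config$jitter > 0) {
      amp <- config$jitter * config$grid_pitch / 2
      gx <- matrix(pmin(config$extent, pmax(0, gx + runif(n * n, -amp, amp))), n, n)
      gy <- matrix(pmin(config$extent, pmax(0, gy + runif(n * n, -amp, amp))), n, n)
    }
    rows <- list(); rid <- 0
    seg <- function(x1, y1, x2, y2) {
      rid <<- rid + 1
      data.frame(id = sprintf("r%04d", rid), seq = 1:2,
                 x = c(x1, x2), y = c(y1, y2), stringsAsFactors = FALSE)
    }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j < n) rows[[length(rows) + 1]] <-
            seg(gx[i, j], gy[i, j], gx[i, j + 1], gy[i, j + 1])
        if (i < n) rows[[length(rows) + 1]] <-
            seg(gx[i, j], gy[i, j], gx[i + 1, j], gy[i + 1, j])
      }
    }
    roads <- as_roads(do.call(rbind, rows))
    # spanning check (jitter preserves topology, but enforce anyway)
    g <- suppressWarnings(build_graph(roads))
    while (g$n_components > 1) {
      comp <- igraph::components(g$graph)$membership
      in1 <- comp == 1
      d <- outer(seq_len(nrow(g$nodes))[in1], seq_len(nrow(g$nodes))[!in1],
                 function(a, b) sqrt((g$nodes$x[a] - g$nodes$x[b])^2 +
                                     (g$nodes$y[a] - g$nodes$y[b])^2))
      hit <- arrayInd(which.min(d), dim(d))
      a <- which(in1)[hit[1]]; b <- which(!in1)[hit[2]]
      rid <- rid + 1
      link <- data.frame(id = sprintf("r%04d", rid), seq = 1:2,
                         x = c(g$nodes$x[a], g$nodes$x[b]),
                         y = c(g$nodes$y[a], g$nodes$y[b]))
      roads <- as_roads(rbind(roads_long(roads), link))
      g <- suppressWarnings(build_graph(roads))
    }
    roads
  })
}

# back-convert a roads layer to long vertex form
roads_long <- function(roads) {
  do.call(rbind, lapply(seq_len(nrow(roads)), function(k) {
    m <- roads$geometry[[k]]
    data.frame(id = roads$id[k], seq = seq_len(nrow(m)),
               x = m[, 1], y = m[, 2], stringsAsFactors = FALSE)
  }))
}

truncnorm15 <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(n, mean, sd)
    out <- c(out, draw[draw >= 1 & draw <= 5])
  }
  out[seq_len(n)]
}

# mixture location sampler: center-Gaussian with prob `clustering`, else
# uniform over the extent
facility_locations <- function(m, clustering, extent) {
  cx <- extent / 2
  clustered <- runif(m) < clustering
  x <- numeric(m); y <- numeric(m)
  for (i in seq_len(m)) {
    if (clustered[i]) {
      repeat {
        px <- rnorm(1, cx, extent / 8); py <- rnorm(1, cx, extent / 8)
        if (px >= 0 && px <= extent && py >= 0 && py <= extent) break
      }
    } else {
      px <- runif(1, 0, extent); py <- runif(1, 0, extent)
    }
    x[i] <- px; y[i] <- py
  }
  data.frame(x = x, y = y)
}

#' Generate buildings, sports spaces and bus stops
#'
#' Buildings are placed by rejection sampling with acceptance probability
#' `exp(-gradient * r / (extent/2))`, `r` being the distance to the center,
#' which yields the center-to-periphery density attenuation typical of
#' monocentric cities. Each facility category mixes a center-clustered
#' Gaussian component with a uniform component according to its clustering
#' weight; capability grades and attractiveness scores are drawn from the
#' configured distributions. Bus routes are shortest network paths between
#' random peripheral nodes, with stops interpolated every `stop_spacing`
#' meters along them.
#'
#' @param config A [synthetic_city_config()].
#' @param roads A roads layer from [generate_roads()].
#' @return A list of validated `buildings`, `spaces`, `stops` layers.
#' @export
generate_sites <- function(config, roads) {
  ext <- config$extent
  cx <- ext / 2
  buildings <- with_seed(layer_seed(config$seed, 2), {
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < config$n_buildings) {
      m <- max(64, 2 * (config$n_buildings - length(xs)))
      px <- runif(m, 0, ext); py <- runif(m, 0, ext)
      r <- sqrt((px - cx)^2 + (py - cx)^2)
      keep <- runif(m) < exp(-config$building_gradient * r / (ext / 2))
      xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
    }
    as_buildings(data.frame(id = sprintf("b%04d", seq_len(config$n_buildings)),
                            x = xs[seq_len(config$n_buildings)],
                            y = ys[seq_len(config$n_buildings)]))
  })

  spaces <- with_seed(layer_seed(config$seed, 3), {
    parts <- lapply(SPACE_CATEGORIES, function(cat) {
      m <- config$facility_counts[[cat]]
      if (m == 0) return(NULL)
      loc <- facility_locations(m, config$facility_clustering[[cat]], ext)
      data.frame(id = sprintf("s_%s_%02d", cat, seq_len(m)),
                 x = loc$x, y = loc$y, category = cat,
                 capability = sample(1:5, m, replace = TRUE,
                                     prob = config$grade_distribution),
                 attractiveness = truncnorm15(m, config$attractiveness_mean,
                                              config$attractiveness_sd),
                 stringsAsFactors = FALSE)
    })
    as_spaces(do.call(rbind, parts))
  })

  stops <- with_seed(layer_seed(config$seed, 4),
                     generate_stops(config, roads))

  list(buildings = buildings, spaces = spaces, stops = stops)
}

generate_stops <- function(config, roads) {
  g <- suppressWarnings(build_graph(roads))
  band <- config$grid_pitch
  peripheral <- which(g$nodes$x < band | g$nodes$x > config$extent - band |
                      g$nodes$y < band | g$nodes$y > config$extent - band)
  if (length(peripheral) < 2 || config$n_bus_routes == 0) {
    return(as_stops(data.frame(id = "t0001",
                               x = config$extent / 2, y = config$extent / 2)))
  }
  pts <- list()
  for (r in seq_len(config$n_bus_routes)) {
    ends <- sample(peripheral, 2)
    path <- igraph::shortest_paths(g$graph,
                                   from = g$nodes$name[ends[1]],
                                   to = g$nodes$name[ends[2]],
                                   weights = igraph::E(g$graph)$length)$vpath[[1]]
    nm <- igraph::as_ids(path)
    idx <- match(nm, g$nodes$name)
    px <- g$nodes$x[idx]; py <- g$nodes$y[idx]
    seglen <- sqrt(diff(px)^2 + diff(py)^2)
    cum <- c(0, cumsum(seglen))
    at <- seq(0, cum[length(cum)], by = config$stop_spacing)
    sx <- approx(cum, px, xout = at, ties = "ordered")$y
    sy <- approx(cum, py, xout = at, ties = "ordered")$y
    pts[[r]] <- data.frame(x = sx, y = sy)
  }
  all <- do.call(rbind, pts)
  # drop stops duplicated across routes (shared corridor)
  key <- paste(round(all$x, 3), round(all$y, 3))
  all <- all[!duplicated(key), , drop = FALSE]
  as_stops(data.frame(id = sprintf("t%04d", seq_len(nrow(all))),
                      x = all$x, y = all$y))
}

#' Generate a complete synthetic city
#'
#' Convenience wrapper running [generate_roads()] then [generate_sites()].
#'
#' @param config A [synthetic_city_config()].
#' @return A list with validated `buildings`, `spaces`, `stops`, `roads`
#'   layers and the `config`, ready for [run_pipeline()].
#' @examples
#' city <- generate_city(synthetic_city_config(seed = 7, n_buildings = 50))
#' nrow(city$buildings)
#' @export
generate_city <- function(config = synthetic_city_config()) {
  roads <- generate_roads(config)
  sites <- generate_sites(config, roads)
  c(sites, list(roads = roads, config = config))
}

#' Generate a city with a tunable walk/bus score correlation
#'
#' Builds a synthetic city in which a share `rho_target` of the facilities
#' is co-located with bus stops (with a small positional jitter), while the
#' remainder is placed uniformly. As `rho_target` grows, walking-favorable
#' and bus-favorable locations increasingly coincide, so the correlation
#' between walking and bus equity scores rises. This is a monotone control
#' of the correlation, not an exact one: the realized r-squared depends on
#' the whole urban form, and only its ordering in `rho_target` is
#' guaranteed on average.
#'
#' @param config A [synthetic_city_config()].
#' @param rho_target Number in [0, 1].
#' @return A dataset list as from [generate_city()].
#' @export
plant_correlation_scenario <- function(config, rho_target) {
  stopifnot(length(rho_target) == 1, rho_target >= 0, rho_target <= 1)
  roads <- generate_roads(config)
  sites <- generate_sites(config, roads)
  stops <- sites$stops
  spaces <- with_seed(layer_seed(config$seed, 5), {
    s <- sites$spaces
    co <- runif(nrow(s)) < rho_target
    if (any(co)) {
      pick <- sample(seq_len(nrow(stops)), sum(co), replace = TRUE)
      s$x[co] <- pmin(config$extent, pmax(0, stops$x[pick] + rnorm(sum(co), 0, 50)))
      s$y[co] <- pmin(config$extent, pmax(0, stops$y[pick] + rnorm(sum(co), 0, 50)))
    }
    if (any(!co)) {
      s$x[!co] <- runif(sum(!co), 0, config$extent)
      s$y[!co] <- runif(sum(!co), 0, config$extent)
    }
    as_spaces(s)
  })
  list(buildings = sites$buildings, spaces = spaces, stops = stops,
       roads = roads, config = config)
}
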