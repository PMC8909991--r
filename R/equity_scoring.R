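#' Gaussian travel-time decay
#'
#' The weight a facility contributes falls off with travel time following a
#' simplified Gaussian kernel, `exp(-0.5 * (t / t0)^2)`, where `t0` is the
#' mode's time horizon (15 min walking, 30 min bus). At `t = 0` the weight
#' is 1; at `t = t0` it is `exp(-1/2)`; it decreases strictly in `t`.
#'
#' @param t Travel time in minutes (vectorized, must be >= 0).
#' @param t0 Time horizon in minutes (> 0).
#' @return Weights in (0, 1].
#' @examples
#' gaussian_decay(0, 15)        # 1
#' gaussian_decay(15, 15)       # exp(-0.5)
#' @export
gaussian_decay <- function(t, t0) {
  if (!is.numeric(t) || any(t < 0, na.rm = TRUE)) {
    stop("travel time t must be non-negative")
  }
  if (!is.numeric(t0) || length(t0) != 1 || !is.finite(t0) || t0 <= 0) {
    stop("t0 must be a single positive number")
  }
  exp(-0.5 * (t / t0)^2)
}

zero_scores <- function() setNames(numeric(length(SPACE_CATEGORIES)), SPACE_CATEGORIES)

sum_by_category <- function(categories, contributions) {
  out <- zero_scores()
  if (length(contributions)) {
    s <- tapply(contributions, factor(categories, levels = SPACE_CATEGORIES), sum)
    s[is.na(s)] <- 0
    out[names(s)] <- s
  }
  out
}

# Shared walking-score kernel: door-to-door walking minutes building x space,
# then the decay-weighted capability x attractiveness sum per category.
walk_score_matrix <- function(prep, spaces, config) {
  mins <- walk_minutes(walk_meters(prep, "buildings", "spaces"), config)
  b_ok <- snapped_of(prep, "buildings")
  scores <- matrix(0, length(b_ok), length(SPACE_CATEGORIES),
                   dimnames = list(names(b_ok), SPACE_CATEGORIES))
  w_base <- spaces$capability * spaces$attractiveness
  for (j in seq_along(b_ok)) {
    if (!b_ok[j]) next
    t <- mins[j, ]
    in_range <- is.finite(t) & t <= config$t0_walk + TIME_EPS_MIN
    contrib <- w_base[in_range] * gaussian_decay(t[in_range], config$t0_walk)
    scores[j, ] <- sum_by_category(spaces$category[in_range], contrib)
  }
  scores
}

# Shared bus-score kernel. Catchments (stop count N and mean walk time w)
# are computed around every building (600 m) and space (400 m); the
# in-vehicle leg p_ij takes the best stop pair; trips inside
# [bus_window_low, t0_bus] contribute S * P * G(T) * N_i * N_j.
bus_score_matrix <- function(prep, spaces, config) {
  b_ok <- snapped_of(prep, "buildings")
  scores <- matrix(0, length(b_ok), length(SPACE_CATEGORIES),
                   dimnames = list(names(b_ok), SPACE_CATEGORIES))
  stops <- prep$snaps[prep$idx$stops, , drop = FALSE]
  if (nrow(stops) == 0) return(scores)

  if (config$catchment_metric == "euclidean") {
    bs <- prep$snaps[prep$idx$buildings, , drop = FALSE]
    sp <- prep$snaps[prep$idx$spaces, , drop = FALSE]
    m_bt <- outer(seq_len(nrow(bs)), seq_len(nrow(stops)),
                  function(i, j) sqrt((bs$x[i] - stops$x[j])^2 +
                                      (bs$y[i] - stops$y[j])^2))
    m_st <- outer(seq_len(nrow(sp)), seq_len(nrow(stops)),
                  function(i, j) sqrt((sp$x[i] - stops$x[j])^2 +
                                      (sp$y[i] - stops$y[j])^2))
    dimnames(m_bt) <- list(bs$id, stops$id)
    dimnames(m_st) <- list(sp$id, stops$id)
  } else {
    m_bt <- walk_meters(prep, "buildings", "stops")
    m_st <- walk_meters(prep, "spaces", "stops")
  }
  stop_net <- net_meters(prep, "stops", "stops")

  b_in <- is.finite(m_bt) & m_bt <= config$building_catchment_radius + RADIUS_EPS_M
  s_in <- is.finite(m_st) & m_st <= config$space_catchment_radius + RADIUS_EPS_M
  w_b <- vapply(seq_len(nrow(m_bt)), function(j) {
    if (any(b_in[j, ])) mean(walk_minutes(m_bt[j, b_in[j, ]], config)) else NA_real_
  }, 0)
  w_s <- vapply(seq_len(nrow(m_st)), function(i) {
    if (any(s_in[i, ])) mean(walk_minutes(m_st[i, s_in[i, ]], config)) else NA_real_
  }, 0)
  n_b <- rowSums(b_in)
  n_s <- rowSums(s_in)
  w_base <- spaces$capability * spaces$attractiveness

  for (j in seq_along(b_ok)) {
    if (!b_ok[j] || n_b[j] == 0) next
    bstops <- which(b_in[j, ])
    t_ij <- rep(Inf, nrow(spaces))
    for (i in seq_len(nrow(spaces))) {
      if (n_s[i] == 0) next
      p_m <- min(stop_net[bstops, s_in[i, ], drop = FALSE])
      if (!is.finite(p_m)) next
      t_ij[i] <- w_b[j] + bus_minutes(p_m, config) + w_s[i]
    }
    in_win <- is.finite(t_ij) & t_ij <= config$t0_bus + TIME_EPS_MIN &
      t_ij >= config$bus_window_low - TIME_EPS_MIN
    contrib <- w_base[in_win] * gaussian_decay(t_ij[in_win], config$t0_bus) *
      n_s[in_win] * n_b[j]
    scores[j, ] <- sum_by_category(spaces$category[in_win], contrib)
  }
  scores
}

score_prep <- function(buildings, spaces, stops, graph, config) {
  groups <- list(buildings = buildings[, c("id", "x", "y")],
                 spaces = spaces[, c("id", "x", "y")])
  if (!is.null(stops) && nrow(stops) > 0) {
    groups$stops <- stops[, c("id", "x", "y")]
  } else {
    groups$stops <- data.frame(id = character(), x = numeric(), y = numeric())
  }
  prepare_routing(graph, groups, config)
}

#' Walking-mode equity score of one building
#'
#' For each facility category, sums `S_i * P_i * G(t_ij)` over the sports
#' spaces reachable within the walking horizon, where `S_i` is the 1-5
#' service-capability grade, `P_i` the 1-5 attractiveness score, `t_ij` the
#' door-to-door walking time and `G` the [gaussian_decay()] kernel with
#' `t0 = config$t0_walk`.
#'
#' @param building A list or one-row data frame with `x`, `y`.
#' @param spaces A sports-space layer (see [as_spaces()]).
#' @param graph A [build_graph()] result.
#' @param config A [mode_config()].
#' @return Named numeric over the four categories. A building that cannot
#'   be snapped to the network scores zero everywhere and carries
#'   `attr(, "unreachable") = TRUE`.
#' @export
walking_equity <- function(building, spaces, graph, config = mode_config()) {
  b <- data.frame(id = "b", x = building$x, y = building$y)
  prep <- score_prep(b, spaces, NULL, graph, config)
  out <- walk_score_matrix(prep, spaces, config)[1, ]
  if (!snapped_of(prep, "buildings")[["b"]]) attr(out, "unreachable") <- TRUE
  out
}

#' Bus-mode equity score of one building
#'
#' For each facility category, sums `S_i * P_i * G(T_ij) * N_i * N_j` over
#' the sports spaces whose composed bus travel time `T_ij = w_i + p_ij +
#' w_j` falls inside the bus window, with `G` using `t0 = config$t0_bus`.
#' `N_j`/`w_j` count and average the walk to the bus stops within 600 m of
#' the building, `N_i`/`w_i` those within 400 m of the space, and `p_ij` is
#' the best in-vehicle connection between the two stop sets. A building
#' with no stop in range scores zero in every category.
#'
#' @inheritParams walking_equity
#' @param stops A bus-stop layer.
#' @return Named numeric over the four categories.
#' @export
bus_equity <- function(building, spaces, stops, graph, config = mode_config()) {
  b <- data.frame(id = "b", x = building$x, y = building$y)
  prep <- score_prep(b, spaces, stops, graph, config)
  out <- bus_score_matrix(prep, spaces, config)[1, ]
  if (!snapped_of(prep, "buildings")[["b"]]) attr(out, "unreachable") <- TRUE
  out
}

#' Combine walking and bus scores
#'
#' The two modes are summed per category: total equity is the value of the
#' space reachable within the 15-minute walking circle plus that reachable
#' within the 30-minute bus circle.
#'
#' @param walk,bus Named numeric vectors over the same categories.
#' @return Named numeric, elementwise sum.
#' @export
combine_modes <- function(walk, bus) {
  if (!setequal(names(walk), names(bus))) {
    stop("walking and bus scores cover different categories")
  }
  walk + bus[names(walk)]
}

#' Standardize combined scores across facility categories
#'
#' The four facility categories are treated as equally important: raw
#' combined scores are rescaled per category before being averaged into an
#' overall value. Three schemes are available:
#'
#' * `mean_equalize` (default): each category is scaled by (grand mean of
#'   the four category means) / (its own mean), so all category means become
#'   equal while within-category ratios are preserved.
#' * `minmax_0_100`: per-category min-max rescaling to 0-100.
#' * `zscore_shifted`: per-category z-scores shifted so the minimum is 0.
#'
#' A category whose scores are all zero is left at zero with a warning
#' (its rescaling is undefined).
#'
#' @param records Data frame with columns `building_id`, `category`,
#'   `combined_score` (plus any others, preserved).
#' @param scheme Standardization scheme name.
#' @return `records` with a `standardized_score` column filled; the scheme
#'   is recorded in `attr(, "scheme")`.
#' @export
standardize_records <- function(records,
                                scheme = c("mean_equalize", "minmax_0_100",
                                           "zscore_shifted")) {
  scheme <- match.arg(scheme)
  if (length(unique(records$building_id)) < 2) {
    stop("standardization needs at least 2 buildings")
  }
  if (!setequal(unique(records$category), SPACE_CATEGORIES)) {
    stop("records must cover exactly the four facility categories")
  }
  records$standardized_score <- NA_real_
  if (scheme == "mean_equalize") {
    means <- tapply(records$combined_score, records$category, mean)
    grand <- mean(means)
    for (cat in SPACE_CATEGORIES) {
      rows <- records$category == cat
      if (means[[cat]] == 0) {
        warning(sprintf(
          "category %s has all-zero scores; left at zero (mean_equalize undefined)",
          cat))
        records$standardized_score[rows] <- 0
      } else {
        records$standardized_score[rows] <-
          records$combined_score[rows] * grand / means[[cat]]
      }
    }
  } else if (scheme == "minmax_0_100") {
    for (cat in SPACE_CATEGORIES) {
      rows <- records$category == cat
      v <- records$combined_score[rows]
      rng <- max(v) - min(v)
      if (rng == 0) {
        warning(sprintf("category %s has constant scores; standardized to 0", cat))
        records$standardized_score[rows] <- 0
      } else {
        records$standardized_score[rows] <- (v - min(v)) / rng * 100
      }
    }
  } else {
    for (cat in SPACE_CATEGORIES) {
      rows <- records$category == cat
      v <- records$combined_score[rows]
      if (sd(v) == 0) {
        warning(sprintf("category %s has constant scores; standardized to 0", cat))
        records$standardized_score[rows] <- 0
      } else {
        z <- (v - mean(v)) / sd(v)
        records$standardized_score[rows] <- z - min(z)
      }
    }
  }
  attr(records, "scheme") <- scheme
  records
}

#' Per-building overall equity value
#'
#' Averages the four standardized category scores of each building, so the
#' overall value lives on the same scale as the category values.
#'
#' @param records Standardized records from [standardize_records()].
#' @return Data frame with `building_id` and `overall_score`.
#' @export
overall_score <- function(records) {
  counts <- table(records$building_id)
  if (any(counts != length(SPACE_CATEGORIES))) {
    stop("every building needs a standardized score for all four categories")
  }
  if (anyNA(records$standardized_score)) {
    stop("standardized scores missing; run standardize_records() first")
  }
  agg <- aggregate(standardized_score ~ building_id, data = records, FUN = mean)
  names(agg) <- c("building_id", "overall_score")
  agg[order(agg$building_id), , drop = FALSE]
}
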