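#' Descriptive summary of a score distribution
#'
#' Sample statistics in the style used to describe equity-score
#' distributions: mean, median (midpoint convention for even n), sample
#' (n-1) standard deviation, extremes and quartiles, plus a skew flag set
#' when the mean exceeds the median — the signature of the right-skewed
#' score distributions where many buildings score low and few score high.
#'
#' @param x Numeric vector, length >= 2.
#' @return A one-row data frame: `n`, `mean`, `median`, `std`, `min`,
#'   `q25`, `q75`, `max`, `skew_flag`.
#' @export
summarize_equity <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 finite values to summarize")
  m <- mean(x); md <- median(x)
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  data.frame(n = length(x), mean = m, median = md, std = sd(x),
             min = min(x), q25 = q[1], q75 = q[2], max = max(x),
             skew_flag = m > md)
}

#' Pearson correlation between walking and bus scores
#'
#' Pairs the two mode scores by building and reports Pearson's r, its
#' square, and the two-sided p-value from the exact t transform with n-2
#' degrees of freedom. When either vector has zero variance the
#' correlation is undefined and the row is flagged.
#'
#' @param walk,bus Paired numeric vectors (same buildings, same order),
#'   length >= 3.
#' @return A one-row data frame: `n`, `r`, `r_squared`, `p_value`,
#'   `defined`.
#' @export
mode_correlation <- function(walk, bus) {
  if (length(walk) != length(bus)) stop("walk and bus scores must be paired")
  ok <- is.finite(walk) & is.finite(bus)
  walk <- walk[ok]; bus <- bus[ok]
  if (length(walk) < 3) stop("need at least 3 paired observations")
  if (sd(walk) == 0 || sd(bus) == 0) {
    return(data.frame(n = length(walk), r = NA_real_, r_squared = NA_real_,
                      p_value = NA_real_, defined = FALSE))
  }
  ct <- cor.test(walk, bus, method = "pearson")
  r <- unname(ct$estimate)
  data.frame(n = length(walk), r = r, r_squared = r^2,
             p_value = ct$p.value, defined = TRUE)
}

#' Quantile classification for choropleth-style mapping
#'
#' Splits scores into `k` quantile-bounded classes (1 = lowest). Values
#' equal to a class boundary go to the lower class. Degenerate inputs with
#' heavy ties collapse duplicated boundaries with a warning; an all-equal
#' vector yields a single occupied class.
#'
#' @param x Numeric scores.
#' @param k Number of classes, `2 <= k <= length(x)`.
#' @return Integer class labels per value, with the class boundaries in
#'   `attr(, "boundaries")`.
#' @export
classify_quantiles <- function(x, k) {
  if (k < 2) stop("k must be at least 2")
  if (k > length(x)) stop("more classes than observations")
  br <- quantile(x, probs = seq(0, 1, length.out = k + 1), names = FALSE)
  ubr <- unique(br)
  if (length(ubr) < length(br)) {
    warning("tied quantile boundaries collapsed; fewer than k classes occupied")
  }
  if (length(ubr) < 2) {
    out <- rep(1L, length(x))
    attr(out, "boundaries") <- br
    return(out)
  }
  out <- as.integer(cut(x, breaks = ubr, include.lowest = TRUE, right = TRUE,
                        labels = FALSE))
  attr(out, "boundaries") <- br
  out
}

validate_dataset <- function(dataset) {
  need <- c("buildings", "spaces", "stops", "roads")
  missing <- setdiff(need, names(dataset))
  if (length(missing)) {
    stop("dataset is missing layers: ", paste(missing, collapse = ", "))
  }
  dataset
}

#' Run the full equity-measurement pipeline
#'
#' Orchestrates every stage on a validated dataset: build the road graph,
#' snap buildings/spaces/stops onto it, compute walking-mode and bus-mode
#' scores per building and category, sum the modes, standardize across
#' categories, and derive the per-building overall value together with
#' distribution summaries and the walking-versus-bus correlation per
#' category. The pipeline consumes no randomness: identical inputs give
#' identical outputs.
#'
#' Buildings farther than `max_snap_distance` from the road network cannot
#' be scored; they are excluded from the records and all statistics and
#' listed in the result.
#'
#' @param dataset A list with layers `buildings`, `spaces`, `stops`,
#'   `roads`, e.g. from [generate_city()] or [read_layers()].
#' @param config A [mode_config()].
#' @param scheme Standardization scheme, see [standardize_records()].
#' @return An `equity_result`: `records` (one row per building x category
#'   with walk/bus/combined/standardized scores and coordinates),
#'   `overall_records` (per-building `"overall"` rows), `overall`
#'   (building_id, overall_score), `summaries`, `correlations`,
#'   `excluded` (unsnappable building ids), `std_factors` (per-category
#'   scaling used by `mean_equalize`), `config`, `scheme`, `graph_report`.
#' @examples
#' \donttest{
#' city <- generate_city(synthetic_city_config(seed = 3, n_buildings = 60))
#' res <- run_pipeline(city)
#' res$summaries
#' }
#' @export
run_pipeline <- function(dataset, config = mode_config(),
                         scheme = "mean_equalize") {
  dataset <- validate_dataset(dataset)
  buildings <- dataset$buildings; spaces <- dataset$spaces
  stops <- dataset$stops; roads <- dataset$roads

  graph <- suppressWarnings(build_graph(roads))
  prep <- score_prep(buildings, spaces, stops, graph, config)
  snapped <- snapped_of(prep, "buildings")
  excluded <- names(snapped)[!snapped]

  walk <- walk_score_matrix(prep, spaces, config)
  bus <- bus_score_matrix(prep, spaces, config)
  keep <- snapped
  walk <- walk[keep, , drop = FALSE]
  bus <- bus[keep, , drop = FALSE]
  kept_b <- buildings[buildings$id %in% rownames(walk), , drop = FALSE]
  kept_b <- kept_b[match(rownames(walk), kept_b$id), , drop = FALSE]
  if (nrow(kept_b) < 2) stop("fewer than 2 buildings could be snapped to the network")

  records <- data.frame(
    building_id = rep(kept_b$id, times = length(SPACE_CATEGORIES)),
    x = rep(kept_b$x, times = length(SPACE_CATEGORIES)),
    y = rep(kept_b$y, times = length(SPACE_CATEGORIES)),
    category = rep(SPACE_CATEGORIES, each = nrow(kept_b)),
    walk_score = as.vector(walk),
    bus_score = as.vector(bus),
    stringsAsFactors = FALSE)
  records$combined_score <- records$walk_score + records$bus_score
  records <- standardize_records(records, scheme)
  overall <- overall_score(records)

  std_factors <- NULL
  if (scheme == "mean_equalize") {
    means <- tapply(records$combined_score, records$category, mean)
    grand <- mean(means)
    std_factors <- setNames(ifelse(means == 0, 0, grand / means), names(means))
  }

  overall_records <- data.frame(
    building_id = kept_b$id, x = kept_b$x, y = kept_b$y,
    category = "overall",
    walk_score = rowSums(walk), bus_score = rowSums(bus),
    combined_score = rowSums(walk) + rowSums(bus),
    standardized_score = overall$overall_score[match(kept_b$id, overall$building_id)],
    stringsAsFactors = FALSE)

  summaries <- do.call(rbind, lapply(c(SPACE_CATEGORIES, "overall"), function(cat) {
    v <- if (cat == "overall") overall$overall_score
         else records$standardized_score[records$category == cat]
    cbind(category = cat, summarize_equity(v))
  }))

  correlations <- do.call(rbind, lapply(c(SPACE_CATEGORIES, "overall"), function(cat) {
    if (cat == "overall") {
      w <- rowSums(walk); b <- rowSums(bus)
    } else {
      w <- walk[, cat]; b <- bus[, cat]
    }
    cbind(category = cat, mode_correlation(w, b))
  }))

  structure(list(records = records, overall_records = overall_records,
                 overall = overall, summaries = summaries,
                 correlations = correlations, excluded = excluded,
                 std_factors = std_factors, config = config, scheme = scheme,
                 graph_report = list(nodes = nrow(graph$nodes),
                                     edges = nrow(graph$edges),
                                     components = graph$n_components,
                                     unsnapped_buildings = length(excluded))),
            class = "equity_result")
}

#' @export
print.equity_result <- function(x, ...) {
  cat(sprintf("<equity_result> %d buildings scored (%d excluded), scheme %s\n",
              length(unique(x$records$building_id)), length(x$excluded),
              x$scheme))
  s <- x$summaries
  s[, c("mean", "median", "std", "max")] <-
    round(s[, c("mean", "median", "std", "max")], 1)
  print(s[, c("category", "n", "mean", "median", "std", "max", "skew_flag")],
        row.names = FALSE)
  invisible(x)
}

#' Propose intervention sites in the lowest-score decile
#'
#' Selects `n` buildings from the lowest decile of the overall equity
#' score, emulating a planning intervention that converts vacant or
#' under-used land in deprived areas into new squares. Two planning
#' heuristics shape the selection. First, when the bus-stop layer is
#' supplied, candidates inside a stop catchment are avoided: the land
#' stock this intervention draws on (vacant lots, wasteland) is
#' characteristic of weakly served areas, and a site inside a catchment
#' would act through the stop-count-multiplied bus term rather than
#' through neighborhood walking access. Second, sites are spread
#' spatially (greedy max-min distance, seeded at the worst-scoring
#' building): a new facility serves its whole neighborhood, so piling
#' several onto one deprived cluster over-serves it while leaving other
#' weak zones untouched.
#'
#' @param result An `equity_result` from [run_pipeline()].
#' @param n Number of sites. Default 5.
#' @param stops Optional bus-stop layer; when given, candidates within
#'   `stop_radius` of a stop are used only if too few remain otherwise.
#' @param stop_radius Meters; default 400, the facility stop-catchment
#'   radius.
#' @return A data frame of building ids and coordinates.
#' @export
propose_square_sites <- function(result, n = 5, stops = NULL,
                                 stop_radius = 400) {
  ov <- result$overall
  cutoff <- quantile(ov$overall_score, 0.10, names = FALSE)
  low <- ov[ov$overall_score <= cutoff, , drop = FALSE]
  if (nrow(low) < n) {
    ov <- ov[order(ov$overall_score, ov$building_id), , drop = FALSE]
    low <- ov[seq_len(min(n, nrow(ov))), , drop = FALSE]
  }
  recs <- result$overall_records
  low <- merge(low, recs[, c("building_id", "x", "y")], by = "building_id")
  if (!is.null(stops) && nrow(stops) > 0) {
    d_stop <- vapply(seq_len(nrow(low)), function(i) {
      min(sqrt((low$x[i] - stops$x)^2 + (low$y[i] - stops$y)^2))
    }, 0)
    if (sum(d_stop > stop_radius) >= n) {
      low <- low[d_stop > stop_radius, , drop = FALSE]
    }
  }
  low <- low[order(low$overall_score, low$building_id), , drop = FALSE]
  chosen <- 1L
  while (length(chosen) < min(n, nrow(low))) {
    d_min <- vapply(seq_len(nrow(low)), function(i) {
      if (i %in% chosen) return(-Inf)
      min(sqrt((low$x[i] - low$x[chosen])^2 + (low$y[i] - low$y[chosen])^2))
    }, 0)
    chosen <- c(chosen, which.max(d_min))
  }
  out <- low[chosen, c("building_id", "x", "y")]
  rownames(out) <- NULL
  out
}

#' Compare equity before and after adding facilities
#'
#' Recomputes the full pipeline on a base dataset and on the same dataset
#' augmented with new sports spaces (and optionally new bus stops), with
#' identical configuration, and reports per-category before/after
#' distribution summaries and their deltas. To keep the two runs on one
#' scale, both are summarized on combined scores rescaled by the BASE
#' run's `mean_equalize` category factors — the intervention changes the
#' scores, not the yardstick.
#'
#' @param dataset Base dataset (see [run_pipeline()]).
#' @param added_spaces A data frame of new spaces, validated by
#'   [as_spaces()]; must be non-empty.
#' @param added_stops Optional data frame of new bus stops.
#' @param config A [mode_config()].
#' @return An `intervention_report`: per-category `before`/`after`
#'   summaries, `deltas` (mean, median, std), `n_added_facilities`, and
#'   the two full `equity_result`s.
#' @export
run_intervention <- function(dataset, added_spaces, added_stops = NULL,
                             config = mode_config()) {
  dataset <- validate_dataset(dataset)
  if (is.null(added_spaces) || nrow(added_spaces) == 0) {
    stop("intervention requires at least one added facility")
  }
  added_spaces <- as_spaces(added_spaces)
  if (any(added_spaces$id %in% dataset$spaces$id)) {
    stop("added space ids clash with existing spaces")
  }
  aug <- dataset
  aug$spaces <- as_spaces(rbind(dataset$spaces[, names(added_spaces)],
                                added_spaces))
  if (!is.null(added_stops) && nrow(added_stops) > 0) {
    added_stops <- as_stops(added_stops)
    if (any(added_stops$id %in% dataset$stops$id)) {
      stop("added stop ids clash with existing stops")
    }
    aug$stops <- as_stops(rbind(dataset$stops[, names(added_stops)], added_stops))
  }

  before <- run_pipeline(dataset, config, scheme = "mean_equalize")
  after <- run_pipeline(aug, config, scheme = "mean_equalize")
  common <- intersect(unique(before$records$building_id),
                      unique(after$records$building_id))
  factors <- before$std_factors

  per_cat <- lapply(SPACE_CATEGORIES, function(cat) {
    vb <- before$records[before$records$category == cat &
                         before$records$building_id %in% common, ]
    va <- after$records[after$records$category == cat &
                        after$records$building_id %in% common, ]
    f <- factors[[cat]]
    sb <- summarize_equity(vb$combined_score * f)
    sa <- summarize_equity(va$combined_score * f)
    list(category = cat, before = sb, after = sa,
         deltas = c(mean = sa$mean - sb$mean,
                    median = sa$median - sb$median,
                    std = sa$std - sb$std))
  })
  names(per_cat) <- SPACE_CATEGORIES
  structure(list(categories = per_cat,
                 n_added_facilities = nrow(added_spaces),
                 n_added_stops = if (is.null(added_stops)) 0 else nrow(added_stops),
                 before = before, after = after),
            class = "intervention_report")
}

#' @export
print.intervention_report <- function(x, ...) {
  cat(sprintf("<intervention_report> +%d facilities, +%d stops\n",
              x$n_added_facilities, x$n_added_stops))
  for (cat_ in names(x$categories)) {
    d <- x$categories[[cat_]]$deltas
    cat(sprintf("  %-15s delta mean %+.2f, median %+.2f, std %+.2f\n",
                cat_, d["mean"], d["median"], d["std"]))
  }
  invisible(x)
}
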