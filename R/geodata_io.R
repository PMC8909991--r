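#' @name layers
#' @title Validated spatial layers
#'
#' @description
#' The pipeline works on four point/line layers in one planar-projected
#' coordinate system (meters): residential buildings (points), public sports
#' spaces (points with a category, a 1-5 service-capability grade and a 1-5
#' attractiveness score), bus stops (points) and road centerlines
#' (polylines). The `as_*()` constructors validate plain data frames into
#' these layers; [read_layers()] builds them from GeoJSON or CSV files.
#'
#' Validation is two-tiered. Structural defects a caller must fix are hard
#' errors naming the offending record: a missing category or capability, a
#' capability outside the integer grades 1-5, an attractiveness outside
#' [1, 5], a duplicated id, an empty layer. Records that are merely unusable
#' (non-finite coordinates, degenerate zero-length roads) are dropped and
#' reported: the dropped rows are attached to the result as
#' `attr(layer, "rejects")`, a data frame of `id` and `reason`, so that
#' accepted plus rejected always account for every input record.
#'
#' @param x A data frame. Buildings and stops need columns `id`, `x`, `y`;
#'   spaces additionally `category` (one of `"park"`, `"square"`,
#'   `"fitness_center"`, `"sports_field"`), `capability` and
#'   `attractiveness`; roads are in long vertex form with columns `id`,
#'   `seq`, `x`, `y` (one row per polyline vertex, ordered by `seq`).
#' @return A validated data frame; roads gain a `geometry` list column of
#'   two-column vertex matrices and a `length_m` column.
NULL

reject_frame <- function(id = character(), reason = character()) {
  data.frame(id = as.character(id), reason = as.character(reason),
             stringsAsFactors = FALSE)
}

check_ids <- function(id, layer) {
  if (anyNA(id) || any(!nzchar(id))) {
    stop(sprintf("%s layer has missing ids", layer))
  }
  if (anyDuplicated(id)) {
    stop(sprintf("%s layer has duplicated ids: %s", layer,
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  invisible(id)
}

require_columns <- function(x, cols, layer) {
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop(sprintf("%s layer is missing required columns: %s", layer,
                 paste(missing, collapse = ", ")))
  }
}

drop_bad_coords <- function(x, layer) {
  bad <- !is.finite(x$x) | !is.finite(x$y)
  rejects <- reject_frame(x$id[bad],
                          rep("non-finite coordinates", sum(bad)))
  list(kept = x[!bad, , drop = FALSE], rejects = rejects)
}

finish_layer <- function(x, rejects, layer) {
  if (nrow(x) == 0) {
    stop(sprintf("%s layer is empty after validation", layer))
  }
  rownames(x) <- NULL
  attr(x, "rejects") <- rejects
  x
}

#' @rdname layers
#' @export
as_buildings <- function(x) {
  x <- as.data.frame(x)
  require_columns(x, c("id", "x", "y"), "buildings")
  x$id <- as.character(x$id)
  check_ids(x$id, "buildings")
  parts <- drop_bad_coords(x[, c("id", "x", "y")], "buildings")
  finish_layer(parts$kept, parts$rejects, "buildings")
}

#' @rdname layers
#' @export
as_stops <- function(x) {
  x <- as.data.frame(x)
  require_columns(x, c("id", "x", "y"), "bus stops")
  x$id <- as.character(x$id)
  check_ids(x$id, "bus stops")
  parts <- drop_bad_coords(x[, c("id", "x", "y")], "bus stops")
  finish_layer(parts$kept, parts$rejects, "bus stops")
}

#' @rdname layers
#' @export
as_spaces <- function(x) {
  x <- as.data.frame(x)
  require_columns(x, c("id", "x", "y", "category", "capability",
                       "attractiveness"), "sports spaces")
  x$id <- as.character(x$id)
  check_ids(x$id, "sports spaces")
  x$category <- as.character(x$category)

  bad_cat <- is.na(x$category) | !(x$category %in% SPACE_CATEGORIES)
  if (any(bad_cat)) {
    stop(sprintf("sports space %s has invalid category %s (must be one of %s)",
                 x$id[bad_cat][1], x$category[bad_cat][1],
                 paste(SPACE_CATEGORIES, collapse = ", ")))
  }
  cap <- x$capability
  bad_cap <- is.na(cap) | !is.numeric(cap) | cap != round(cap) |
    cap < 1 | cap > 5
  if (any(bad_cap)) {
    stop(sprintf("sports space %s has capability %s outside integer grades 1..5",
                 x$id[bad_cap][1], x$capability[bad_cap][1]))
  }
  x$capability <- as.integer(cap)
  att <- x$attractiveness
  bad_att <- is.na(att) | att < 1 | att > 5
  if (any(bad_att)) {
    stop(sprintf("sports space %s has attractiveness %s outside [1, 5]",
                 x$id[bad_att][1], x$attractiveness[bad_att][1]))
  }
  parts <- drop_bad_coords(
    x[, c("id", "x", "y", "category", "capability", "attractiveness")],
    "sports spaces")
  finish_layer(parts$kept, parts$rejects, "sports spaces")
}

#' @rdname layers
#' @export
as_roads <- function(x) {
  x <- as.data.frame(x)
  require_columns(x, c("id", "seq", "x", "y"), "roads")
  x$id <- as.character(x$id)
  x <- x[order(x$id, x$seq), , drop = FALSE]

  ids <- unique(x$id)
  geoms <- vector("list", length(ids))
  keep <- logical(length(ids))
  reasons <- character(length(ids))
  lengths <- numeric(length(ids))
  for (k in seq_along(ids)) {
    v <- x[x$id == ids[k], c("x", "y"), drop = FALSE]
    m <- as.matrix(v)
    dimnames(m) <- NULL
    if (any(!is.finite(m))) {
      reasons[k] <- "non-finite coordinates"
      next
    }
    if (nrow(m) < 2) {
      reasons[k] <- "fewer than 2 vertices"
      next
    }
    len <- sum(sqrt(rowSums(diff(m)^2)))
    if (len <= 0) {
      reasons[k] <- "zero length"
      next
    }
    keep[k] <- TRUE
    geoms[[k]] <- m
    lengths[k] <- len
  }
  rejects <- reject_frame(ids[!keep], reasons[!keep])
  out <- data.frame(id = ids[keep], length_m = lengths[keep],
                    stringsAsFactors = FALSE)
  out$geometry <- geoms[keep]
  finish_layer(out, rejects, "roads")
}

# Refuse coordinates that look geographic (degrees): every metric city
# extent exceeds these bounds, while any real lon/lat layer sits inside
# them. Applied at file ingestion only, so small synthetic fixtures built
# in code are unaffected.
check_projected <- function(x, y, layer) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) && all(abs(x) <= 180) && all(abs(y) <= 90)) {
    stop(sprintf(paste0(
      "%s layer looks like geographic lon/lat coordinates; ",
      "reproject all layers to a planar metric CRS (meters) first"), layer))
  }
}

read_geojson_points <- function(path, layer) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop(sprintf("%s: not a GeoJSON FeatureCollection", path))
  rows <- lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    if (is.null(f$geometry) || !identical(f$geometry$type, "Point")) {
      stop(sprintf("%s feature %d: expected Point geometry", layer, i))
    }
    p <- f$properties
    id <- if (!is.null(p$id)) p$id else if (!is.null(f$id)) f$id else i
    c(list(id = as.character(id),
           x = as.numeric(f$geometry$coordinates[[1]]),
           y = as.numeric(f$geometry$coordinates[[2]])),
      p[setdiff(names(p), c("id", "x", "y"))])
  })
  nm <- unique(unlist(lapply(rows, names)))
  out <- lapply(nm, function(col) {
    vals <- lapply(rows, function(r) if (is.null(r[[col]])) NA else r[[col]])
    unlist(vals, use.names = FALSE)
  })
  names(out) <- nm
  as.data.frame(out, stringsAsFactors = FALSE)
}

read_geojson_lines <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop(sprintf("%s: not a GeoJSON FeatureCollection", path))
  rows <- list()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    if (is.null(f$geometry) || !identical(f$geometry$type, "LineString")) {
      stop(sprintf("roads feature %d: expected LineString geometry", i))
    }
    id <- if (!is.null(f$properties$id)) as.character(f$properties$id) else as.character(i)
    coords <- f$geometry$coordinates
    rows[[i]] <- data.frame(
      id = id,
      seq = seq_along(coords),
      x = vapply(coords, function(c) as.numeric(c[[1]]), 0),
      y = vapply(coords, function(c) as.numeric(c[[2]]), 0),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read the four spatial layers from GeoJSON or CSV
#'
#' @description
#' Ingests buildings, sports spaces, bus stops and roads from files and
#' returns validated layers. GeoJSON layers are RFC 7946 FeatureCollections
#' (Point features for buildings/spaces/stops, LineString for roads) with
#' attributes in `properties`; CSV layers are headered tables with `x`, `y`
#' columns plus attributes, roads in long vertex form (`id`, `seq`, `x`,
#' `y`). Coordinates must be planar-projected meters: input that looks like
#' geographic lon/lat degrees is refused with instructions to reproject.
#'
#' @param buildings,spaces,stops,roads File paths, one per layer.
#' @param format `"geojson"` or `"csv"` (applies to all four files).
#' @param quiet Suppress the per-layer count messages.
#' @return A list with validated elements `buildings`, `spaces`, `stops`,
#'   `roads`, each carrying an `attr(, "rejects")` data frame of dropped
#'   records, suitable for [run_pipeline()].
#' @seealso [as_buildings()] for the validation rules, [write_results()]
#' @export
read_layers <- function(buildings, spaces, stops, roads,
                        format = c("geojson", "csv"), quiet = FALSE) {
  format <- match.arg(format)
  paths <- c(buildings = buildings, spaces = spaces, stops = stops, roads = roads)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input files not found: ", paste(missing, collapse = ", "))
  }
  if (format == "geojson") {
    b_raw <- read_geojson_points(buildings, "buildings")
    s_raw <- read_geojson_points(spaces, "sports spaces")
    t_raw <- read_geojson_points(stops, "bus stops")
    r_raw <- read_geojson_lines(roads)
  } else {
    b_raw <- read.csv(buildings, stringsAsFactors = FALSE)
    s_raw <- read.csv(spaces, stringsAsFactors = FALSE)
    t_raw <- read.csv(stops, stringsAsFactors = FALSE)
    r_raw <- read.csv(roads, stringsAsFactors = FALSE)
  }
  for (layer in list(list(b_raw, "buildings"), list(s_raw, "sports spaces"),
                     list(t_raw, "bus stops"), list(r_raw, "roads"))) {
    check_projected(layer[[1]]$x, layer[[1]]$y, layer[[2]])
  }
  out <- list(buildings = as_buildings(b_raw), spaces = as_spaces(s_raw),
              stops = as_stops(t_raw), roads = as_roads(r_raw))
  if (!quiet) {
    for (nm in names(out)) {
      nrej <- nrow(attr(out[[nm]], "rejects"))
      message(sprintf("%s: %d accepted, %d rejected", nm, nrow(out[[nm]]), nrej))
      if (nrej > 0) {
        rej <- attr(out[[nm]], "rejects")
        for (i in seq_len(nrej)) {
          message(sprintf("  rejected %s: %s", rej$id[i], rej$reason[i]))
        }
      }
    }
  }
  out
}

results_frame <- function(records) {
  cols <- c("building_id", "x", "y", "category", "walk_score", "bus_score",
            "combined_score", "standardized_score")
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  }
  records[, cols]
}

#' Export equity records to GeoJSON or CSV
#'
#' Writes one row/feature per (building, category) plus one `"overall"` row
#' per building, carrying the building geometry so any GIS can map the
#' scores. GeoJSON output embeds a `metadata` member recording the CRS
#' label, the [mode_config()] used and the standardization scheme.
#'
#' @param result An `equity_result` from [run_pipeline()], or a data frame
#'   of records with columns `building_id`, `x`, `y`, `category`,
#'   `walk_score`, `bus_score`, `combined_score`, `standardized_score`
#'   (categories may include `"overall"`).
#' @param path Output file path.
#' @param format `"geojson"` or `"csv"`.
#' @param crs Free-text label of the projected CRS, stored in the metadata.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(result, path, format = c("geojson", "csv"),
                          crs = "local-metric") {
  format <- match.arg(format)
  if (inherits(result, "equity_result")) {
    records <- rbind(results_frame(result$records),
                     results_frame(result$overall_records))
    meta <- list(crs = crs, mode_config = unclass(result$config),
                 standardization = result$scheme,
                 software = "equicity")
  } else {
    records <- results_frame(as.data.frame(result))
    meta <- list(crs = crs, software = "equicity")
  }
  if (nrow(records) == 0) stop("no records to write")
  records <- records[order(records$building_id, records$category), ]
  rownames(records) <- NULL

  if (format == "csv") {
    write.csv(records, path, row.names = FALSE)
  } else {
    features <- lapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = c(r$x, r$y)),
           properties = list(id = r$building_id, category = r$category,
                             walk_score = r$walk_score, bus_score = r$bus_score,
                             combined_score = r$combined_score,
                             standardized_score = r$standardized_score))
    })
    gj <- list(type = "FeatureCollection", metadata = meta, features = features)
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = FALSE)
  }
  invisible(path)
}

#' Read back an exported results file
#'
#' @param path File written by [write_results()].
#' @param format `"geojson"` or `"csv"`.
#' @return A data frame with one row per exported record.
#' @export
read_results <- function(path, format = c("geojson", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    out <- read.csv(path, stringsAsFactors = FALSE)
    out$building_id <- as.character(out$building_id)
    out$category <- as.character(out$category)
    return(out)
  }
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(gj$features, function(f) {
    p <- f$properties
    data.frame(building_id = as.character(p$id),
               x = as.numeric(f$geometry$coordinates[[1]]),
               y = as.numeric(f$geometry$coordinates[[2]]),
               category = as.character(p$category),
               walk_score = as.numeric(p$walk_score),
               bus_score = as.numeric(p$bus_score),
               combined_score = as.numeric(p$combined_score),
               standardized_score = as.numeric(p$standardized_score),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
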