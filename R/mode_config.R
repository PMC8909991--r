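#' Travel-mode configuration
#'
#' Bundles the travel parameters used throughout the pipeline: walking and bus
#' speeds, the time horizons of the 15-minute walking circle and the 30-minute
#' bus circle, the bus-stop catchment radii around facilities and buildings,
#' and the maximum distance at which an off-network point may be snapped onto
#' the road graph.
#'
#' @param walk_speed Walking speed in m/s. Default 1.2.
#' @param bus_speed Bus in-vehicle speed in m/s. Default 10 km/h.
#' @param t0_walk Walking time horizon in minutes (the decay scale and cutoff
#'   of the walking mode). Default 15.
#' @param t0_bus Bus time horizon in minutes. Default 30.
#' @param space_catchment_radius Radius in meters within which bus stops are
#'   counted around a sports space. Default 400.
#' @param building_catchment_radius Radius in meters within which bus stops
#'   are counted around a residential building. Default 600.
#' @param max_snap_distance Maximum meters from the road network at which a
#'   point can still be attached to it. Default 500.
#' @param bus_window_low Lower bound in minutes on bus travel times admitted
#'   to the bus-mode score. The default 0 includes every trip up to `t0_bus`;
#'   setting it to `t0_walk` restricts the bus sum to trips beyond the walking
#'   circle.
#' @param catchment_metric Either `"network"` (stop catchments measured as
#'   walking distance along the road graph, the default) or `"euclidean"`
#'   (straight-line).
#'
#' @return An object of class `mode_config`.
#' @examples
#' cfg <- mode_config()
#' cfg$t0_walk
#' @export
mode_config <- function(walk_speed = 1.2,
                        bus_speed = 10 / 3.6,
                        t0_walk = 15,
                        t0_bus = 30,
                        space_catchment_radius = 400,
                        building_catchment_radius = 600,
                        max_snap_distance = 500,
                        bus_window_low = 0,
                        catchment_metric = c("network", "euclidean")) {
  catchment_metric <- match.arg(catchment_metric)
  num <- c(walk_speed = walk_speed, bus_speed = bus_speed,
           t0_walk = t0_walk, t0_bus = t0_bus,
           space_catchment_radius = space_catchment_radius,
           building_catchment_radius = building_catchment_radius,
           max_snap_distance = max_snap_distance)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all mode_config parameters must be finite and strictly positive")
  }
  if (!is.finite(bus_window_low) || bus_window_low < 0) {
    stop("bus_window_low must be finite and >= 0")
  }
  if (t0_bus < t0_walk) {
    stop("t0_bus must be >= t0_walk")
  }
  structure(
    list(walk_speed = walk_speed, bus_speed = bus_speed,
         t0_walk = t0_walk, t0_bus = t0_bus,
         space_catchment_radius = space_catchment_radius,
         building_catchment_radius = building_catchment_radius,
         max_snap_distance = max_snap_distance,
         bus_window_low = bus_window_low,
         catchment_metric = catchment_metric),
    class = "mode_config"
  )
}

#' @export
print.mode_config <- function(x, ...) {
  cat("<mode_config>\n")
  cat(sprintf("  walking: %.2f m/s, horizon %g min\n", x$walk_speed, x$t0_walk))
  cat(sprintf("  bus:     %.2f m/s, horizon %g min, window low %g min\n",
              x$bus_speed, x$t0_bus, x$bus_window_low))
  cat(sprintf("  stop catchments: %g m (space) / %g m (building), %s distance\n",
              x$space_catchment_radius, x$building_catchment_radius,
              x$catchment_metric))
  cat(sprintf("  max snap distance: %g m\n", x$max_snap_distance))
  invisible(x)
}

# minutes needed to walk `meters` at the configured speed
walk_minutes <- function(meters, config) meters / config$walk_speed / 60

# minutes needed to ride `meters` at the configured bus speed
bus_minutes <- function(meters, config) meters / config$bus_speed / 60
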