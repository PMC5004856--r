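#' @keywords internal
"_PACKAGE"

# Mean Earth radius (km) used throughout: haversine distances, metric
# conversion in the advection equations, and contour arc lengths.
EARTH_RADIUS_KM <- 6371.0

#' Metres per degree of latitude
#'
#' @param radius_km Earth radius in kilometres.
#' @return Metres spanned by one degree of latitude on a sphere.
#' @export
m_per_deg_lat <- function(radius_km = EARTH_RADIUS_KM) {
  pi * radius_km * 1000 / 180
}

#' Metres per degree of longitude at a latitude
#'
#' @param lat Latitude in degrees.
#' @inheritParams m_per_deg_lat
#' @export
m_per_deg_lon <- function(lat, radius_km = EARTH_RADIUS_KM) {
  m_per_deg_lat(radius_km) * cos(lat * pi / 180)
}

#' Regular longitude/latitude grid specification
#'
#' Describes the node-registered grid on which velocity fields live:
#' a regular lon/lat mesh (default 0.08 degree spacing, matching common
#' global-model output resolution), a set of z-levels (metres, positive
#' down) and a daily snapshot axis.
#'
#' @param lon_min,lon_max,lat_min,lat_max Domain bounds in degrees.
#' @param spacing Grid spacing in degrees (applies to both axes).
#' @param z_levels Depths of the vertical levels in metres, positive down,
#'   strictly increasing. See [levitus_levels()] for the standard spacing.
#' @param time_origin Calendar date of the first snapshot (`Date` or
#'   coercible string).
#' @param n_snapshots Number of velocity snapshots.
#' @param snapshot_interval Days between snapshots (default 1, i.e. daily
#'   averaged fields).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max,
                      spacing = 0.08,
                      z_levels,
                      time_origin = as.Date("2012-01-04"),
                      n_snapshots = 1,
                      snapshot_interval = 1) {
  stopifnot(spacing > 0, lon_max > lon_min, lat_max > lat_min,
            lat_min > -90, lat_max < 90,
            n_snapshots >= 1, snapshot_interval > 0)
  z_levels <- as.numeric(z_levels)
  if (length(z_levels) < 1 || any(diff(z_levels) <= 0))
    stop("z_levels must be non-empty and strictly increasing")
  nlon <- floor((lon_max - lon_min) / spacing + 1e-9) + 1L
  nlat <- floor((lat_max - lat_min) / spacing + 1e-9) + 1L
  g <- list(
    lon_min = lon_min, lat_min = lat_min,
    spacing = spacing,
    nlon = nlon, nlat = nlat,
    lon = lon_min + (seq_len(nlon) - 1L) * spacing,
    lat = lat_min + (seq_len(nlat) - 1L) * spacing,
    z_levels = z_levels,
    time_origin = as.Date(time_origin),
    n_snapshots = as.integer(n_snapshots),
    snapshot_interval = snapshot_interval
  )
  g$lon_max <- g$lon[nlon]
  g$lat_max <- g$lat[nlat]
  # snapshot times in days since time_origin
  g$snapshot_days <- (seq_len(n_snapshots) - 1L) * snapshot_interval
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d nodes, %.3f deg spacing\n",
              x$nlon, x$nlat, x$spacing))
  cat(sprintf("  lon [%.3f, %.3f], lat [%.3f, %.3f]\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  cat(sprintf("  %d z-levels (%g-%g m), %d snapshots every %g d from %s\n",
              length(x$z_levels), min(x$z_levels), max(x$z_levels),
              x$n_snapshots, x$snapshot_interval,
              format(x$time_origin)))
  invisible(x)
}

#' Standard z-level depths between two bounds
#'
#' Ocean-model outputs distributed on fixed depth levels conventionally
#' coarsen with depth: one level every 50 m between 150 and 300 m, every
#' 100 m between 300 and 1500 m, every 250 m between 1500 and 2000 m, and
#' every 500 m between 2000 and 5500 m. This returns the levels of that
#' convention that fall inside `[min_depth, max_depth]`.
#'
#' @param min_depth,max_depth Depth range in metres, positive down, with
#'   `150 <= min_depth < max_depth <= 5500`.
#' @return Strictly increasing numeric vector of level depths (m).
#' @examples
#' levitus_levels(300, 1500)   # 13 levels, 100 m apart
#' levitus_levels(150, 300)    # 150 200 250 300
#' @export
levitus_levels <- function(min_depth, max_depth) {
  if (!is.numeric(min_depth) || !is.numeric(max_depth) ||
      !(min_depth > 0) || !(min_depth < max_depth))
    stop("need 0 < min_depth < max_depth")
  if (min_depth < 150 || max_depth > 5500)
    stop("unsupported depth range: the level convention covers 150-5500 m")
  bands <- rbind(c(150, 300, 50),
                 c(300, 1500, 100),
                 c(1500, 2000, 250),
                 c(2000, 5500, 500))
  levels <- unlist(lapply(seq_len(nrow(bands)), function(i)
    seq(bands[i, 1], bands[i, 2], by = bands[i, 3])))
  levels <- sort(unique(levels))
  out <- levels[levels >= min_depth - 1e-9 & levels <= max_depth + 1e-9]
  if (length(out) == 0)
    stop("no standard levels inside [", min_depth, ", ", max_depth, "]")
  out
}

# Continuous (1-based) fractional grid indices for lon/lat queries.
.grid_index <- function(grid, lon, lat) {
  list(gx = (lon - grid$lon_min) / grid$spacing + 1,
       gy = (lat - grid$lat_min) / grid$spacing + 1)
}

# TRUE where a lon/lat query lies inside the grid bounds.
.in_bounds <- function(grid, lon, lat) {
  lon >= grid$lon_min & lon <= grid$lon_max &
    lat >= grid$lat_min & lat <= grid$lat_max
}
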