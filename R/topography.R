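#' Idealized guyot (table-mount) topography
#'
#' Builds a radially symmetric flat-topped seamount on a grid: seafloor
#' depth equals `summit_depth` inside `summit_radius` of the centre,
#' increases linearly with great-circle distance to `base_depth` at
#' `base_radius`, and equals `basin_depth` beyond. The defaults emulate a
#' guyot whose flanks span roughly 600-2000 m depth.
#'
#' @param grid A [grid_spec()].
#' @param centre_lon,centre_lat Seamount centre (degrees); must lie inside
#'   the grid.
#' @param summit_depth,base_depth Depth (m, positive down) of the flat
#'   summit and of the foot of the flank.
#' @param summit_radius,base_radius Radii (km) of the summit plateau and
#'   of the seamount base.
#' @param basin_depth Background seafloor depth (m) beyond the seamount.
#' @return An object of class `topography`: the grid plus a
#'   `nlon x nlat` matrix of seafloor depths (m, positive down).
#' @export
guyot_topography <- function(grid,
                             centre_lon, centre_lat,
                             summit_depth = 600, base_depth = 2000,
                             summit_radius = 20, base_radius = 45,
                             basin_depth = 2200) {
  stopifnot(inherits(grid, "grid_spec"),
            summit_depth < base_depth, summit_radius < base_radius,
            base_depth <= basin_depth)
  if (!.in_bounds(grid, centre_lon, centre_lat))
    stop("seamount centre lies outside the grid")
  lonm <- matrix(grid$lon, grid$nlon, grid$nlat)
  latm <- matrix(grid$lat, grid$nlon, grid$nlat, byrow = TRUE)
  r <- haversine_km(lonm, latm, centre_lon, centre_lat)
  depth <- basin_depth + numeric(length(r))
  flank <- r > summit_radius & r < base_radius
  depth[r <= summit_radius] <- summit_depth
  depth[flank] <- summit_depth +
    (r[flank] - summit_radius) / (base_radius - summit_radius) *
      (base_depth - summit_depth)
  depth[r >= base_radius] <- basin_depth
  dim(depth) <- c(grid$nlon, grid$nlat)
  structure(list(grid = grid, depth = depth,
                 centre = c(lon = centre_lon, lat = centre_lat),
                 summit_depth = summit_depth, base_depth = base_depth,
                 summit_radius = summit_radius, base_radius = base_radius,
                 basin_depth = basin_depth),
            class = "topography")
}

#' @export
print.topography <- function(x, ...) {
  cat(sprintf("<topography> %d x %d cells, depth %g-%g m\n",
              nrow(x$depth), ncol(x$depth), min(x$depth), max(x$depth)))
  invisible(x)
}

#' Seafloor depth at arbitrary positions
#'
#' Bilinear interpolation of the gridded seafloor depth; used to decide
#' whether a particle position is inside the seamount/land (seafloor
#' shallower than the particle).
#'
#' @param topo A [guyot_topography()] (or any `topography`).
#' @param lon,lat Query positions (degrees), vectorised.
#' @return Seafloor depth in metres (positive down); `NA` outside the grid.
#' @export
topo_depth_at <- function(topo, lon, lat) {
  grid <- topo$grid
  out <- rep(NA_real_, length(lon))
  ok <- .in_bounds(grid, lon, lat)
  if (!any(ok)) return(out)
  gi <- .grid_index(grid, lon[ok], lat[ok])
  out[ok] <- .bilinear_slice(topo$depth, gi$gx, gi$gy)
  out
}

# Per-level node validity: a node is invalid for a z-level when the
# seafloor there is shallower than the level (i.e. the level is inside
# the seamount), or the node is land (depth <= 0).
.validity_mask <- function(topo, z_levels) {
  v <- array(TRUE, dim = c(dim(topo$depth), length(z_levels)))
  for (k in seq_along(z_levels))
    v[, , k] <- topo$depth >= z_levels[k] & topo$depth > 0
  v
}
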