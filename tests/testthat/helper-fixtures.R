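# Shared fixtures: tiny analytic field series and cached expensive runs.

# A series with spatially uniform (u0, v0) everywhere, flat deep basin.
uniform_series <- function(u0, v0, spacing = 0.1, half = 1,
                           z_levels = 100, n_snapshots = 3,
                           lat0 = 0) {
  g <- grid_spec(-half, half, lat0 - half, lat0 + half, spacing = spacing,
                 z_levels = z_levels, n_snapshots = n_snapshots)
  nl <- length(z_levels)
  structure(list(
    grid = g, topo = NULL, params = NULL,
    u = array(u0, c(g$nlon, g$nlat, nl, n_snapshots)),
    v = array(v0, c(g$nlon, g$nlat, nl, n_snapshots)),
    valid = array(TRUE, c(g$nlon, g$nlat, nl)), seed = NULL),
    class = "velocity_field_series")
}

# Solid-body rotation about (0, lat0): u = -w*y, v = +w*x in local
# metres (y measured as mlat * lat). Linear in lon/lat, so bicubic and
# bilinear interpolation reproduce it exactly.
rotation_series <- function(omega = 1e-5, spacing = 0.05, half = 1,
                            n_snapshots = 10) {
  g <- grid_spec(-half, half, -half, half, spacing = spacing,
                 z_levels = 100, n_snapshots = n_snapshots)
  mlat <- m_per_deg_lat()
  ym <- matrix(g$lat, g$nlon, g$nlat, byrow = TRUE) * mlat
  xm <- matrix(g$lon, g$nlon, g$nlat) * mlat
  structure(list(
    grid = g, topo = NULL, params = NULL,
    u = array(rep(-omega * ym, n_snapshots),
              c(g$nlon, g$nlat, 1, n_snapshots)),
    v = array(rep(omega * xm, n_snapshots),
              c(g$nlon, g$nlat, 1, n_snapshots)),
    valid = array(TRUE, c(g$nlon, g$nlat, 1)), seed = NULL),
    class = "velocity_field_series")
}

# Straight-line synthetic tracks for rasterization tests.
line_track <- function(lons, lats) {
  structure(list(id = 1L, lon = lons, lat = lats,
                 day = seq_along(lons) - 1, depth = 100,
                 status = "active"),
            class = "disp_track")
}

# Cache for expensive stochastic experiments, shared across test files
# within one session.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}
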