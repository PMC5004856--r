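test_that("levitus_levels follows the banded spacing convention", {
  expect_equal(levitus_levels(300, 1500), seq(300, 1500, by = 100))
  expect_length(levitus_levels(300, 1500), 13)
  expect_equal(levitus_levels(150, 300), c(150, 200, 250, 300))
  # band boundaries appear once and spacing changes across bands
  lv <- levitus_levels(150, 5500)
  expect_true(all(diff(lv) > 0))
  expect_equal(sum(lv == 300), 1)
  expect_equal(diff(lv)[lv[-length(lv)] >= 2000], rep(500, 7))
  expect_error(levitus_levels(700, 700), "min_depth")
  expect_error(levitus_levels(100, 500), "unsupported")
  expect_error(levitus_levels(1000, 6000), "unsupported")
})

test_that("guyot topography is radially symmetric and linear on the flank", {
  g <- grid_spec(-12, -10, 56.5, 58.5, spacing = 0.05,
                 z_levels = c(700, 1000, 1500), n_snapshots = 1)
  topo <- guyot_topography(g, -11, 57.5, summit_depth = 600,
                           base_depth = 2000, summit_radius = 20,
                           base_radius = 45, basin_depth = 2200)
  expect_equal(topo_depth_at(topo, -11, 57.5), 600)
  # point mid-way down the flank: depth is the mid-point by linearity
  mid_r <- (20 + 45) / 2
  dlat <- mid_r / 111.1949266
  expect_equal(topo_depth_at(topo, -11, 57.5 + dlat), (600 + 2000) / 2,
               tolerance = 1e-2)
  # radial symmetry: same depth east and north of the centre
  dlon <- mid_r / (111.1949266 * cos(57.5 * pi / 180))
  expect_equal(topo_depth_at(topo, -11 + dlon, 57.5),
               topo_depth_at(topo, -11, 57.5 + dlat), tolerance = 1e-2)
  expect_error(guyot_topography(g, -20, 57.5), "outside")
})

test_that("degenerate eddy configuration reduces to the background flow", {
  g <- grid_spec(-1, 1, -1, 1, spacing = 0.1, z_levels = 100,
                 n_snapshots = 2)
  topo <- guyot_topography(g, 0, 0, summit_depth = 2100,
                           base_depth = 2150, summit_radius = 5,
                           base_radius = 10, basin_depth = 2200)
  p <- eddy_field_params(amplitude = 0, n_eddies = 0,
                         background_u = 0.1, background_v = 0, seed = 1)
  s <- generate_velocity_series(g, topo, p)
  expect_true(all(abs(s$u - 0.1) < 1e-12))
  expect_true(all(abs(s$v) < 1e-12))
})

test_that("same seed gives bit-identical fields, different seed differs", {
  a <- synthetic_series(n_snapshots = 3, seed = 42, half_width_deg = 1.5)
  b <- synthetic_series(n_snapshots = 3, seed = 42, half_width_deg = 1.5)
  c <- synthetic_series(n_snapshots = 3, seed = 43, half_width_deg = 1.5)
  expect_identical(a$u, b$u)
  expect_identical(a$v, b$v)
  expect_false(identical(a$u, c$u))
})

test_that("eddy velocity fields are discretely divergence-free", {
  # single static vortex over a flat basin (no taper active, no drift)
  g <- grid_spec(-2, 2, -2, 2, spacing = 0.08, z_levels = 1000,
                 n_snapshots = 1)
  topo <- guyot_topography(g, 0, 0, summit_depth = 2100,
                           base_depth = 2150, summit_radius = 5,
                           base_radius = 10, basin_depth = 2200)
  p <- eddy_field_params(amplitude = 5000, n_eddies = 1,
                         drift_km_day = 0, amp_sd = 0,
                         background_u = 0, background_v = 0, seed = 7)
  s <- generate_velocity_series(g, topo, p)
  u <- s$u[, , 1, 1]; v <- s$v[, , 1, 1]
  lat_mid <- (g$lat_min + g$lat_max) / 2
  dx <- g$spacing * m_per_deg_lon(lat_mid)
  dy <- g$spacing * m_per_deg_lat()
  i <- 3:(g$nlon - 2); j <- 3:(g$nlat - 2)
  div <- (u[i + 1, j] - u[i - 1, j]) / (2 * dx) +
    (v[i, j + 1] - v[i, j - 1]) / (2 * dy)
  expect_lt(max(abs(div)), 1e-10 * max(abs(u)))
})

test_that("spatial speed variability reproduces the depth ordering", {
  # greatest at 1000 m, least at 1500 m (with 700 m in between)
  s <- synthetic_series(z_levels = c(700, 1000, 1500), n_snapshots = 4,
                        seed = 5)
  sds <- vapply(1:3, function(l) {
    sel <- s$valid[, , l]
    stats::sd(sqrt(s$u[, , l, 1][sel]^2 + s$v[, , l, 1][sel]^2))
  }, numeric(1))
  expect_gt(sds[2], sds[1])
  expect_gt(sds[1], sds[3])
})

test_that("no valid cell sits where the seafloor is shallower than the level", {
  s <- synthetic_series(z_levels = c(700, 1000, 1500), n_snapshots = 2,
                        seed = 2)
  for (l in 1:3) {
    bad <- s$valid[, , l] & s$topo$depth < s$grid$z_levels[l]
    expect_false(any(bad))
    # invalid cells carry zero velocity
    expect_true(all(s$u[, , l, 1][!s$valid[, , l]] == 0))
    expect_true(all(s$v[, , l, 1][!s$valid[, , l]] == 0))
  }
})
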