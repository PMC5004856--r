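test_that("rasterization marks exactly the traversed cells once", {
  spec <- raster_spec(0, 0, nx = 10, ny = 10, cell = 0.1)
  # straight equatorial track crossing 3 cells
  tr <- line_track(c(0.05, 0.25), c(0.05, 0.05))
  r <- rasterize_tracks(tr, spec)
  expect_equal(sum(r$counts), 3)
  expect_equal(r$counts[1:3, 1], rep(1L, 3))
  # looping back through a visited cell still counts once
  loop <- line_track(c(0.05, 0.25, 0.05), c(0.05, 0.05, 0.05))
  r2 <- rasterize_tracks(loop, spec)
  expect_equal(max(r2$counts), 1)
  expect_equal(sum(r2$counts), 3)
  # empty input: all-zero raster
  s <- uniform_series(0, 0)
  ts <- run_release_set(s, data.frame(lon = 1, lat = 1, depth = 100,
                                      release_day = 0)[0, ],
                        tracker_config(pld = 2))
  expect_equal(sum(rasterize_tracks(ts, spec)$counts), 0)
})

test_that("rasterization agrees with a dense point-sampling oracle", {
  spec <- raster_spec(-1, -1, nx = 50, ny = 50, cell = 0.04)
  set.seed(11)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    lons <- cumsum(c(stats::runif(1, -0.5, 0.5),
                     stats::runif(n - 1, -0.15, 0.15)))
    lats <- cumsum(c(stats::runif(1, -0.5, 0.5),
                     stats::runif(n - 1, -0.15, 0.15)))
    r <- rasterize_tracks(line_track(lons, lats), spec)
    got <- which(r$counts == 1, arr.ind = TRUE)
    got_keys <- paste(got[, 1] - 1 +
                        round((r$spec$lon_min - spec$lon_min) / spec$cell),
                      got[, 2] - 1 +
                        round((r$spec$lat_min - spec$lat_min) / spec$cell))
    expect_setequal(got_keys, sampled_cells(lons, lats, spec))
  }
})

test_that("raster counts never exceed the number of tracks", {
  s <- synthetic_series(z_levels = 700, n_snapshots = 6, seed = 21,
                        half_width_deg = 1.5)
  pts <- ring_release_points(s$topo, 700, 8)
  pts$release_day <- 0
  ts <- run_release_set(s, pts, tracker_config(timestep = 21600, pld = 5))
  r <- rasterize_tracks(ts, raster_spec_for_grid(s$grid))
  expect_lte(max(r$counts), nrow(ts$meta))
  expect_gt(sum(r$counts), 0)
})

test_that("fuv matches the Pearson oracle and its identities", {
  mk <- function(vals, nx = 2, ny = 2)
    structure(list(counts = matrix(as.integer(vals), nx, ny),
                   spec = raster_spec(0, 0, nx, ny, 0.04)),
              class = "density_raster")
  a <- mk(c(1, 2, 3, 4)); b <- mk(c(2, 1, 4, 3))
  # hand Pearson: r = 0.6, fuv = 1 - 0.36
  f <- fuv(a, b)
  expect_equal(f$r, 0.6)
  expect_equal(f$fuv, 0.64)
  # identity and affine invariance
  expect_equal(fuv(a, a)$fuv, 0)
  expect_equal(fuv(a, mk(c(2, 4, 6, 8)))$fuv, 0)
  expect_equal(fuv(a, mk(c(3, 5, 7, 9)))$fuv, 0)
  # symmetry
  expect_equal(fuv(a, b)$fuv, fuv(b, a)$fuv)
  # zero variance over the compared cells errors
  expect_error(fuv(mk(c(1, 1, 1, 1)), mk(c(1, 2, 1, 2))), "variance")
})

test_that("fuv aligns rasters of different extents by padding zeros", {
  a <- structure(list(counts = matrix(1:4, 2, 2),
                      spec = raster_spec(0, 0, 2, 2, 0.5)),
                 class = "density_raster")
  b <- structure(list(counts = matrix(c(1, 2, 0, 3, 4, 0), 3, 2),
                      spec = raster_spec(0, 0, 3, 2, 0.5)),
                 class = "density_raster")
  f <- fuv(a, b)
  expect_equal(f$n_cells, 4)   # joint-zero cells excluded
  expect_equal(f$r, 1)
})

test_that("fuv envelope takes the 95th percentile per increment", {
  expect_equal(fuv_envelope(c(1, 2), list(0.5, 0.2))$q95, c(0.5, 0.2))
  expect_equal(fuv_envelope(1, list(rep(0.3, 20)))$q95, 0.3)
  set.seed(3)
  draws <- stats::runif(100)
  q <- fuv_envelope(1, list(draws))$q95
  expect_equal(q, stats::quantile(draws, 0.95, type = 7, names = FALSE))
  expect_lt(abs(q - 0.95), 0.04)
  expect_error(fuv_envelope(c(1, 2), list(0.5)), "per increment")
})

test_that("fuv_to_correlation inverts the definition", {
  expect_equal(fuv_to_correlation(0), 1)
  expect_equal(fuv_to_correlation(1), 0)
  expect_equal(fuv_to_correlation(0.05), sqrt(0.95))
  expect_equal(round(fuv_to_correlation(0.05), 4), 0.9747)
  expect_error(fuv_to_correlation(1.2), "0, 1")
})
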