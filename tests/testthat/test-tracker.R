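test_that("interpolation reproduces stored values and hand computations", {
  s <- uniform_series(0.07, -0.03)
  # constant field: same value anywhere, any time
  q <- sample_velocity(s, c(-0.5, 0.33), c(0.2, -0.7), 100, c(0.5, 1.2))
  expect_equal(q$u, c(0.07, 0.07))
  expect_equal(q$v, c(-0.03, -0.03))

  # knot reproduction: exact node/snapshot/level query returns stored value
  g <- grid_spec(-1, 1, -1, 1, spacing = 0.5, z_levels = c(50, 150),
                 n_snapshots = 2)
  u <- array(stats::rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  s2 <- structure(list(grid = g, topo = NULL, u = u, v = u * 0,
                       valid = array(TRUE, c(5, 5, 2)), seed = NULL),
                  class = "velocity_field_series")
  expect_equal(sample_velocity(s2, 0, 0.5, 150, 1)$u, u[3, 4, 2, 2])
  expect_equal(sample_velocity(s2, -0.5, -1, 50, 0)$u, u[2, 1, 1, 1])

  # bilinear mode at a cell centre averages the 4 corners
  u3 <- array(0, c(5, 5, 1, 1)); u3[3, 3, 1, 1] <- 0; u3[4, 3, 1, 1] <- 2
  u3[3, 4, 1, 1] <- 4; u3[4, 4, 1, 1] <- 6
  s3 <- structure(list(grid = grid_spec(-1, 1, -1, 1, spacing = 0.5,
                                        z_levels = 100, n_snapshots = 1),
                       topo = NULL, u = u3, v = u3 * 0,
                       valid = array(TRUE, c(5, 5, 1)), seed = NULL),
                  class = "velocity_field_series")
  expect_equal(sample_velocity(s3, 0.25, 0.25, 100, 0,
                               mode = "linear")$u, 3)

  # out-of-bounds query errors
  expect_error(sample_velocity(s, 5, 0, 100, 0), "outside")
})

test_that("RK4 reproduces the analytic uniform-flow displacement", {
  s <- uniform_series(0.1, 0)
  st <- list(lon = 0, lat = 0, depth = 100, time = 0, status = "active")
  st2 <- rk4_step(s, st, 3600)
  expect_equal(st2$lon, 0.1 * 3600 / m_per_deg_lat(), tolerance = 1e-12)
  expect_equal(st2$lat, 0)
  expect_equal(st2$time, 3600)
  # zero field: fixed point
  s0 <- uniform_series(0, 0)
  st3 <- rk4_step(s0, st, 3600)
  expect_equal(st3$lon, 0)
  expect_equal(st3$lat, 0)
})

test_that("RK4 closes a solid-body rotation orbit and converges at order 4", {
  ss <- rotation_series()
  omega <- 1e-5
  period <- 2 * pi / omega
  cfg <- tracker_config()
  # one full period at period/1000 returns within 1e-3 of the orbit radius
  st <- list(lon = 0.1, lat = 0, depth = 100, time = 0, status = "active")
  for (i in 1:1000) st <- rk4_step(ss, st, period / 1000, cfg)
  r0_km <- 0.1 * m_per_deg_lat() / 1000
  expect_lt(haversine_km(st$lon, st$lat, 0.1, 0), 1e-3 * r0_km)

  # convergence order >= 3.5 over a decade of timesteps (vs fine reference)
  endp <- function(nstep) {
    st <- list(lon = 0.3, lat = 0, depth = 100, time = 0,
               status = "active")
    for (i in seq_len(nstep)) st <- rk4_step(ss, st, period / 4 / nstep, cfg)
    c(st$lon, st$lat)
  }
  ref <- endp(1024)
  errs <- vapply(c(16, 32, 64, 128), function(n)
    sqrt(sum((endp(n) - ref)^2)), numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders >= 3.5))
})

test_that("advection is reversible in a static field", {
  ss <- rotation_series(n_snapshots = 4)
  cfg <- tracker_config()
  st <- list(lon = 0.25, lat = 0.1, depth = 100, time = 0,
             status = "active")
  for (i in 1:50) st <- rk4_step(ss, st, 3600, cfg)
  neg <- ss; neg$u <- -neg$u; neg$v <- -neg$v
  back <- list(lon = st$lon, lat = st$lat, depth = 100, time = 0,
               status = "active")
  for (i in 1:50) back <- rk4_step(neg, back, 3600, cfg)
  expect_lt(haversine_km(back$lon, back$lat, 0.25, 0.1), 1e-5)
})

test_that("tracks honour the daily output contract for every fate", {
  # stationary particle: pld + 1 identical records, active
  s0 <- uniform_series(0, 0, n_snapshots = 11)
  tr <- advect_particle(s0, list(lon = 0, lat = 0, depth = 100), 0,
                        tracker_config(pld = 10))
  expect_length(tr$lon, 11)
  expect_true(all(tr$lon == 0) && all(tr$lat == 0))
  expect_equal(tr$status, "active")

  # uniform eastward flow toward the edge: escapes, frozen afterwards
  se <- uniform_series(0.5, 0, half = 0.5, n_snapshots = 31)
  tre <- advect_particle(se, list(lon = 0.3, lat = 0, depth = 100), 0,
                         tracker_config(pld = 30))
  expect_equal(tre$status, "escaped")
  expect_length(tre$lon, 31)
  frozen <- tre$lon[length(tre$lon)]
  expect_true(sum(tre$lon == frozen) > 1)
  expect_true(frozen <= 0.5)

  # uniform flow at the equator: daily positions colinear, equal spacing
  su <- uniform_series(0.1, 0, n_snapshots = 11)
  tru <- advect_particle(su, list(lon = -0.5, lat = 0, depth = 100), 0,
                         tracker_config(pld = 10))
  expect_equal(tru$status, "active")
  steps <- diff(tru$lon)
  expect_lt(max(abs(steps - steps[1])), 1e-9)
  expect_lt(max(abs(tru$lat)), 1e-12)
})

test_that("release on land errors and releases inside the water run", {
  s <- synthetic_series(z_levels = c(700, 1000), n_snapshots = 3, seed = 3,
                        half_width_deg = 1.5)
  expect_error(
    run_release_set(s, data.frame(lon = -11, lat = 57.5, depth = 1000,
                                  release_day = 0),
                    tracker_config(pld = 2)),
    "seamount")
  pts <- ring_release_points(s$topo, 1000, 4)
  pts$release_day <- 0
  ts <- run_release_set(s, pts, tracker_config(pld = 2))
  expect_equal(nrow(ts$meta), 4)
  expect_equal(length(ts$days), 3)
})

test_that("batch engine matches repeated runs and never visits invalid cells", {
  s <- synthetic_series(z_levels = c(700, 1000), n_snapshots = 8, seed = 4,
                        half_width_deg = 1.5)
  pts <- rbind(ring_release_points(s$topo, 700, 6),
               ring_release_points(s$topo, 1000, 6))
  rel <- pts[rep(1:12, 2), ]
  rel$release_day <- rep(c(0, 2), each = 12)
  cfg <- tracker_config(timestep = 7200, pld = 5)
  a <- run_release_set(s, rel, cfg)
  b <- run_release_set(s, rel, cfg)
  expect_identical(a$lon, b$lon)
  expect_identical(a$meta$status, b$meta$status)
  expect_equal(nrow(a$meta), 24)
  expect_equal(dim(a$lon), c(24L, 6L))
  # no recorded position sits over seafloor shallower than the particle
  # beyond the configured clearance tolerance
  sf <- topo_depth_at(s$topo, as.vector(a$lon), as.vector(a$lat))
  depth <- rep(rel$depth, 6)
  expect_true(all(sf >= depth - cfg$beach_tol_m - 1e-6, na.rm = TRUE))
  # empty design gives an empty collection
  e <- run_release_set(s, rel[0, ], cfg)
  expect_equal(nrow(e$meta), 0)
})
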