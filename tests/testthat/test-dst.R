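test_that("haversine distance matches oracles and identities", {
  # one degree of longitude on the equator, R = 6371 km
  expect_equal(haversine_km(0, 0, 1, 0), 6371 * pi / 180,
               tolerance = 1e-9)
  expect_equal(haversine_km(0, 0, 1, 0), 111.1949, tolerance = 1e-4)
  expect_equal(haversine_km(3, 7, 3, 7), 0)
  expect_equal(haversine_km(-5, 40, 10, 55), haversine_km(10, 55, -5, 40))
  # spherical law of cosines oracle on assorted pairs
  slc <- function(lon1, lat1, lon2, lat2) {
    r <- pi / 180
    6371 * acos(pmin(1, sin(lat1 * r) * sin(lat2 * r) +
                       cos(lat1 * r) * cos(lat2 * r) *
                         cos((lon2 - lon1) * r)))
  }
  set.seed(1)
  for (i in 1:20) {
    p <- stats::runif(4, -60, 60)
    expect_equal(haversine_km(p[1], p[2], p[3], p[4]),
                 slc(p[1], p[2], p[3], p[4]), tolerance = 1e-6)
  }
  skip_if_not_installed("geosphere")
  expect_equal(haversine_km(-11, 57.5, -10, 58),
               geosphere::distHaversine(c(-11, 57.5), c(-10, 58),
                                        r = 6371000) / 1000,
               tolerance = 1e-9)
})

test_that("dst_series compares paired daily positions over days 1..PLD", {
  mk <- function(lons, lats) list(lon = lons, lat = lats,
                                  day = seq_along(lons) - 1)
  a <- mk(rep(0, 6), rep(0, 6))
  expect_equal(dst_series(a, a)$dst_km, rep(0, 5))
  expect_equal(dst_series(a, a)$day, 1:5)
  # two stationary points 0.01 deg apart on the equator
  b <- mk(rep(0.01, 6), rep(0, 6))
  expect_equal(dst_series(a, b)$dst_km,
               rep(haversine_km(0, 0, 0.01, 0), 5))
  expect_equal(dst_series(a, b)$dst_km[1], 1.112, tolerance = 1e-3)
  expect_error(dst_series(a, mk(rep(0, 4), rep(0, 4))), "length")
  # equal advection in a uniform zonal field keeps separation constant
  s <- uniform_series(0.2, 0, n_snapshots = 6)
  cfg <- tracker_config(pld = 5)
  t1 <- advect_particle(s, list(lon = -0.5, lat = 0, depth = 100), 0, cfg)
  t2 <- advect_particle(s, list(lon = -0.45, lat = 0, depth = 100), 0, cfg)
  d <- dst_series(t1, t2)$dst_km
  expect_lt(max(abs(d - d[1])), 1e-6)
})

test_that("pool_dst reports order statistics of the pooled distribution", {
  mk <- function(v) structure(data.frame(day = seq_along(v), dst_km = v),
                              class = c("dst_series", "data.frame"))
  one <- pool_dst(mk(rep(7, 10)))
  expect_equal(one$median_km, 7)
  expect_equal(one$q1, 7)
  expect_equal(one$q3, 7)
  expect_equal(pool_dst(mk(1:5))$median_km, 3)
  # pooled count = n_pairs x PLD
  many <- pool_dst(list(mk(1:10), mk(11:20), mk(21:30)))
  expect_equal(many$n, 30)
  expect_equal(many$median_km, stats::median(1:30))
  # order invariance
  expect_equal(pool_dst(list(mk(21:30), mk(1:10), mk(11:20)))$median_km,
               many$median_km)
  expect_error(pool_dst(list()), "empty")
})

test_that("dst_by_day finds the first independence day", {
  mk <- function(v) structure(data.frame(day = seq_along(v), dst_km = v),
                              class = c("dst_series", "data.frame"))
  # constant below threshold: never independent
  r <- dst_by_day(list(mk(rep(2, 10)), mk(rep(3, 10))), threshold_km = 10)
  expect_true(is.na(r$first_independent_day))
  expect_equal(r$by_day$median_km, rep(2.5, 10))
  # linear growth crossing on a known day: median crosses 10 at day 7
  grow <- lapply(c(1.2, 1.4, 1.6), function(f) mk(f * (1:10)))
  r2 <- dst_by_day(grow, threshold_km = 10)
  expect_equal(r2$first_independent_day, ceiling(10 / 1.4))
  # identical tracks: all-zero medians
  s <- uniform_series(0.1, 0.05, n_snapshots = 4)
  t1 <- advect_particle(s, list(lon = 0, lat = 0, depth = 100), 0,
                        tracker_config(pld = 3))
  r3 <- dst_by_day(list(dst_series(t1, t1)))
  expect_true(all(r3$by_day$median_km == 0))
})
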