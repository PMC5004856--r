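# A finely resolved guyot for geometric invariants.
fine_guyot <- function(centre_lon = -11, centre_lat = 57.5,
                       spacing = 0.02) {
  g <- grid_spec(centre_lon - 1.2, centre_lon + 1.2,
                 centre_lat - 1.2, centre_lat + 1.2, spacing = spacing,
                 z_levels = c(700, 1000, 1500), n_snapshots = 1)
  guyot_topography(g, centre_lon, centre_lat)
}

test_that("ring release points sit on the contour at equal spacing", {
  topo <- fine_guyot()
  pts <- ring_release_points(topo, 1000, 16, clearance_m = 0)
  expect_equal(pts$id, 0:15)
  d <- haversine_km(pts$lon, pts$lat,
                    c(pts$lon[-1], pts$lon[1]), c(pts$lat[-1], pts$lat[1]))
  expect_lt((max(d) - min(d)) / mean(d), 1e-3)
  # topographic depth matches the requested depth well within half the
  # radial depth change per cell
  grad_per_cell <- (2000 - 600) / (45 - 20) *
    (topo$grid$spacing * 111.1949266)
  expect_lt(max(abs(topo_depth_at(topo, pts$lon, pts$lat) - 1000)),
            grad_per_cell / 2)
  # ids run clockwise from north: point 0 north of centre, point 4 east
  expect_gt(pts$lat[1], 57.5)
  expect_lt(abs(pts$lon[1] - (-11)), 0.02)
  expect_gt(pts$lon[5], -11)
  expect_error(ring_release_points(topo, 5000), "contour")
})

test_that("contour offsets follow buffer-radius-in-degrees arc semantics", {
  topo <- fine_guyot()
  pts <- ring_release_points(topo, 1000, 4, clearance_m = 0)
  o <- offset_along_contour(pts[1, ], 0.001, topo)
  expect_equal(haversine_km(pts$lon[1], pts$lat[1], o$lon, o$lat) * 1000,
               0.001 * pi / 180 * 6371 * 1000, tolerance = 1e-3)
  # additivity on the contour: 0.001 then 0.004 equals 0.005
  two <- offset_along_contour(offset_along_contour(pts[1, ], 0.001, topo),
                              0.004, topo)
  one <- offset_along_contour(pts[1, ], 0.005, topo)
  expect_lt(abs(two$lon - one$lon), 1e-9)
  expect_lt(abs(two$lat - one$lat), 1e-9)
  # contour invariance: offset point keeps the baseline depth
  expect_equal(topo_depth_at(topo, o$lon, o$lat), 1000, tolerance = 0.5)
  expect_equal(o$depth, 1000)
  expect_error(offset_along_contour(pts[1, ], 10, topo), "half the contour")
})

test_that("vertical offsets displace depth only", {
  p <- data.frame(id = 0L, lon = -11, lat = 57.4, depth = 1000)
  expect_equal(offset_depth(p, -50)$depth, 950)
  expect_equal(offset_depth(p, -0.1)$depth, 999.9)
  q <- data.frame(id = 0L, lon = -11, lat = 57.4, depth = 200)
  expect_equal(offset_depth(q, -0.1)$depth, 199.9)
  expect_equal(offset_depth(p, 0)$depth, 1000)
  expect_equal(offset_depth(p, -50)$lon, p$lon)
  expect_error(offset_depth(q, -250), "surface")
})

test_that("release schedules reproduce the standard per-year counts", {
  counts <- c(daily = 365, `2-daily` = 183, biweekly = 104, weekly = 52,
              monthly = 12, seasonal = 4)
  for (lab in names(counts)) {
    sch <- build_release_schedule(lab)
    expect_equal(nrow(sch), unname(counts[lab]))
    expect_true(all(diff(sch$release_day) > 0))
    expect_true(all(sch$release_day == floor(sch$release_day)))
    expect_true(all(sch$release_day >= 0 & sch$release_day < 365))
  }
  expect_equal(nrow(build_release_schedule("monthly", n_years = 5)), 60)
  expect_equal(nrow(build_release_schedule(20)), 20)
  expect_error(build_release_schedule("fortnightly"), "unknown")
})

test_that("year combinations enumerate the standard subset counts", {
  yrs <- 2008:2012
  expect_length(year_combinations(yrs, 1), 5)
  expect_length(year_combinations(yrs, 2), 10)
  expect_length(year_combinations(yrs, 3), 10)
  expect_length(year_combinations(yrs, 4), 5)
  expect_length(year_combinations(yrs, 5), 1)
  # lexicographic order and state tagging
  c2 <- year_combinations(yrs, 2, states = nao_states())
  expect_equal(c2[[1]]$years, c(2008, 2009))
  expect_equal(c2[[1]]$states, c("other", "neutral"))
  c3 <- year_combinations(c(2009, 2010, 2012), 3, states = nao_states())
  expect_setequal(c3[[1]]$states,
                  c("neutral", "strong negative", "strong positive"))
  expect_error(year_combinations(yrs, 6), "range")
})

test_that("design enumeration reproduces the printed particle counts", {
  topo <- fine_guyot(spacing = 0.08)
  # spatial test: 16 points x 3 depths x 12 monthly releases x 4 HS
  # increments = 576 baseline tracks, 2880 particles in total
  des <- experiment_design(topo, schedule = build_release_schedule("monthly"),
                           sweep = parameter_sweep("HS"))
  counts <- enumerate_design(des)
  expect_equal(counts$baseline_tracks, 576)
  expect_equal(counts$total, 2880)
  # release-frequency test: 48 locations x 365 daily releases = 17520
  rf <- experiment_design(topo, schedule = build_release_schedule("daily"),
                          sweep = parameter_sweep("RF"))
  expect_equal(enumerate_design(rf)$baseline_tracks, 17520)
  # seasonal increment alone is 192 particles
  expect_equal(48 * 4, 192)
  # zero increments: total equals baseline
  none <- experiment_design(topo,
                            schedule = build_release_schedule("monthly"),
                            sweep = parameter_sweep("HS",
                                                    increments = numeric(0)))
  expect_equal(enumerate_design(none)$total,
               enumerate_design(none)$baseline_tracks)
})

test_that("enumeration matches the realised release table on small designs", {
  topo <- fine_guyot(spacing = 0.08)
  des <- experiment_design(topo, depths = c(700, 1000), n_points = 4,
                           schedule = build_release_schedule("seasonal"),
                           sweep = parameter_sweep("HS",
                                                   increments = c(0.001,
                                                                  0.005)))
  counts <- enumerate_design(des)
  rel <- design_release_table(des)
  expect_equal(nrow(rel), counts$total)
  expect_equal(sum(rel$role == "baseline"), counts$baseline_tracks)
  # schedules validate against the field span instead of silently clipping
  s <- synthetic_series(z_levels = c(700, 1000), n_snapshots = 5, seed = 1,
                        half_width_deg = 1.5)
  expect_error(run_release_set(s, transform(rel, release_day = 300),
                               tracker_config(pld = 10)),
               "span")
})
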