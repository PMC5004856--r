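test_that("threshold crossing matches dense-grid brute force", {
  x <- c(0, 1, 2, 3); y <- c(0, 5, 15, 30)
  r <- fit_threshold_crossing(x, y, 10)
  expect_false(r$extrapolated)
  expect_gt(r$optimal, 1); expect_lt(r$optimal, 2)
  expect_equal(r$optimal, dense_crossing(x, y, 10), tolerance = 1e-3)
})

test_that("crossing handles knot hits, extrapolation and degenerate thresholds", {
  # threshold exactly at a knot value returns that knot's increment
  r <- fit_threshold_crossing(c(0, 1, 2, 3), c(0, 5, 15, 30), 15)
  expect_equal(r$optimal, 2)
  # all statistics below threshold: linear end-slope estimate, flagged
  r2 <- fit_threshold_crossing(c(0, 1, 2), c(0, 1, 2), 10)
  expect_true(r2$extrapolated)
  expect_gt(r2$optimal, 2)
  expect_equal(r2$optimal, 10, tolerance = 1e-3)  # unit end slope
  # threshold 0 with an anchored curve: optimal is the smallest knot
  r3 <- fit_threshold_crossing(c(1, 2, 3), c(5, 15, 30), 0,
                               anchor = c(0, 0))
  expect_equal(r3$optimal, 0)
  expect_error(fit_threshold_crossing(c(1, 1, 2), c(1, 2, 3), 5),
               "duplicate")
  expect_error(fit_threshold_crossing(1, 5, 3), "two knots")
})

test_that("down-crossings locate saturation optima", {
  env <- data.frame(increment = c(4, 52, 183, 365),
                    q95 = c(0.6, 0.2, 0.04, 0.0))
  r <- optimal_from_envelope(env, 0.05)
  expect_false(r$extrapolated)
  expect_gt(r$optimal, 52); expect_lt(r$optimal, 183)
  expect_equal(r$optimal,
               dense_crossing(env$increment, env$q95, 0.05, "down",
                              step = 0.01),
               tolerance = 0.5)
  # all knots already below threshold: smallest increment
  low <- data.frame(increment = c(4, 52), q95 = c(0.01, 0.001))
  expect_equal(optimal_from_envelope(low, 0.05)$optimal, 4)
  # none below: extrapolated flag
  hi <- data.frame(increment = c(4, 52), q95 = c(0.9, 0.8))
  expect_true(optimal_from_envelope(hi, 0.05)$extrapolated)
})

test_that("crossings agree with dense evaluation on random monotone knot sets", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(3:7, 1)
    x <- sort(stats::runif(n, 0, 10))
    y <- cumsum(stats::runif(n, 0, 5))
    th <- stats::runif(1, min(y), max(y))
    r <- fit_threshold_crossing(x, y, th)
    o <- dense_crossing(x, y, th)
    if (!r$extrapolated && !is.na(o))
      expect_equal(r$optimal, o, tolerance = 2e-3)
  }
})
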