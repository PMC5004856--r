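# Packaged stochastic recovery experiments: repeated seeded runs of the
# suite's tests used to verify that the analysis engines recover the
# depth structure built into the synthetic ocean.

#' Horizontal-separation depth-ordering recovery experiment
#'
#' Runs the horizontal-separation test on freshly generated synthetic
#' fields for a sequence of seeds and asks, per seed, whether the
#' recovered optimal separations order as the imposed eddy variability
#' implies: most variable mid-depth (1000 m) smallest, least variable
#' deep level (1500 m) largest, with 700 m in between.
#'
#' @param n_seeds Number of independent seeded runs.
#' @param base_seed First seed; runs use `base_seed + 0:(n_seeds-1)`.
#' @param config A [suite_config()]; `config$seed` is overridden per
#'   run.
#' @param quiet Suppress per-seed progress.
#' @return List with `optima` (n_seeds x 3 matrix of optimal HS per
#'   depth), `medians` (n_seeds x depth x increment array of pooled
#'   median DST in km), `ordered` (logical per seed) and `rate`.
#' @export
run_hs_ordering_experiment <- function(n_seeds = 20, base_seed = 1,
                                       config = suite_config(
                                         spatial_releases = 1),
                                       quiet = TRUE) {
  depths <- config$depths
  stopifnot(length(depths) == 3)
  opt <- matrix(NA_real_, n_seeds, 3,
                dimnames = list(NULL, paste0("d", depths)))
  meds <- array(NA_real_, c(n_seeds, 3, length(config$hs_increments)),
                dimnames = list(NULL, paste0("d", depths),
                                paste0("hs", config$hs_increments)))
  for (i in seq_len(n_seeds)) {
    config$seed <- as.integer(base_seed + i - 1)
    rep_i <- run_sensitivity_suite(config, tests = "HS", quiet = TRUE)
    o <- rep_i$optima
    opt[i, ] <- o$optimal[match(depths, o$depth)]
    for (j in seq_along(depths)) {
      kn <- rep_i$curves$HS[[as.character(depths[j])]]$knots
      meds[i, j, ] <- kn$statistic[-1]   # drop the (baseline, 0) anchor
    }
    if (!quiet)
      message(sprintf("seed %d: %s", config$seed,
                      paste(signif(opt[i, ], 3), collapse = " ")))
  }
  ordered <- opt[, 2] < opt[, 1] & opt[, 1] < opt[, 3]
  list(optima = opt, medians = meds, ordered = ordered,
       rate = mean(ordered, na.rm = TRUE))
}

#' Release-frequency saturation monotonicity experiment
#'
#' For a sequence of seeds, computes the mean FUV between k-per-window
#' release subsets and the daily baseline on synthetic fields, and
#' checks that the seed-averaged FUV is non-increasing in k (more
#' releases saturate the track-density map better).
#'
#' @param n_seeds Number of independent seeded runs.
#' @param base_seed First seed.
#' @param depth Depth band (m) used for the test.
#' @param n_points Release locations (replicates).
#' @param counts Release counts tested against the daily baseline.
#' @param window Days in the release window.
#' @param pld Tracking time (days).
#' @param timestep Tracker timestep (s).
#' @return List with `mean_fuv` (seed-averaged FUV per count, ordered as
#'   `counts`), `fuv` (n_seeds x counts matrix), and
#'   `frac_ordered_pairs`: the fraction of adjacent count pairs whose
#'   seed-averaged FUV is ordered (higher count, lower FUV).
#' @export
run_rf_monotonicity_experiment <- function(n_seeds = 20, base_seed = 1,
                                           depth = 1000,
                                           n_points = 8,
                                           counts = c(2, 5, 9, 15),
                                           window = 30,
                                           pld = 15,
                                           timestep = 10800) {
  fuvs <- matrix(NA_real_, n_seeds, length(counts),
                 dimnames = list(NULL, paste0("k", counts)))
  for (i in seq_len(n_seeds)) {
    seed <- as.integer(base_seed + i - 1)
    series <- synthetic_series(z_levels = depth,
                               n_snapshots = window + pld + 1,
                               seed = seed)
    rspec <- raster_spec_for_grid(series$grid)
    sch <- build_release_schedule("daily", year_length = window)
    pts <- ring_release_points(series$topo, depth, n_points,
                               clearance_m = 150)
    pts$point_id <- pts$id
    rel <- pts[rep(seq_len(nrow(pts)), times = nrow(sch)), ]
    rel$release_day <- rep(sch$release_day, each = nrow(pts))
    ts <- run_release_set(series, rel,
                          tracker_config(timestep = timestep, pld = pld,
                                         beach_tol_m = 60))
    for (j in seq_along(counts)) {
      sub_days <- build_release_schedule(counts[j],
                                         year_length = window)$release_day
      vals <- vapply(pts$point_id, function(p) {
        rows_b <- which(ts$meta$point_id == p)
        rows_i <- which(ts$meta$point_id == p &
                          ts$meta$release_day %in% sub_days)
        fuv(rasterize_tracks(ts[rows_b], rspec),
            rasterize_tracks(ts[rows_i], rspec))$fuv
      }, numeric(1))
      fuvs[i, j] <- mean(vals)
    }
  }
  mean_fuv <- colMeans(fuvs)
  ordered <- diff(mean_fuv) <= 0
  list(mean_fuv = mean_fuv, fuv = fuvs,
       frac_ordered_pairs = mean(ordered))
}
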