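# Orchestration: Courant-number utilities, implied-speed
# back-computation, and the five-test sensitivity suite (timestep,
# release frequency, horizontal and vertical separation, temporal
# range) run end to end on synthetic fields.

#' Courant number
#'
#' C = V * dT / dL: the number of grid cells a parcel moving at speed V
#' covers per timestep. C <= 1 means the simulator is interrogated in
#' every cell along the path.
#'
#' @param speed Mean or maximum current speed (m/s).
#' @param timestep Simulator timestep (s).
#' @param grid_length Grid spacing (m) at the reference latitude.
#' @return The dimensionless Courant number.
#' @export
courant_number <- function(speed, timestep, grid_length) {
  if (any(c(speed, timestep, grid_length) <= 0))
    stop("all Courant inputs must be positive")
  speed * timestep / grid_length
}

#' Implied current speed from a separation and a time
#'
#' velocity = distance / time: relates an optimal horizontal separation
#' (converted to metres) and an optimal timestep to the current speeds
#' the model effectively resolves.
#'
#' @param distance_m Distance in metres.
#' @param time_s Time in seconds.
#' @return Speed in m/s (full precision; reports round to 2 significant
#'   figures).
#' @export
implied_speed <- function(distance_m, time_s) {
  if (any(distance_m <= 0) || any(time_s <= 0))
    stop("distance and time must be positive")
  distance_m / time_s
}

#' Speed statistics over a field level or along trajectories
#'
#' Speed = sqrt(u^2 + v^2), summarised either over all valid nodes of a
#' z-level (all snapshots) or only over the nodes visited by the
#' supplied tracks.
#'
#' @param series A `velocity_field_series`.
#' @param level Index of the z-level (ignored when `tracks` given with
#'   per-track depths).
#' @param tracks Optional `track_set`; restricts the statistics to grid
#'   nodes nearest to any recorded track position.
#' @return List with `mean` and `max` speed (m/s).
#' @export
domain_speed_stats <- function(series, level = 1, tracks = NULL) {
  grid <- series$grid
  if (is.null(tracks)) {
    sel <- series$valid[, , level]
    if (!any(sel)) stop("no valid cells at this level")
    sp <- sqrt(series$u[, , level, , drop = FALSE]^2 +
                 series$v[, , level, , drop = FALSE]^2)
    vals <- apply(sp, 4, function(m) m[sel])
    vals <- as.numeric(vals)
  } else {
    gi <- .grid_index(grid, as.vector(tracks$lon), as.vector(tracks$lat))
    ix <- pmin(pmax(round(gi$gx), 1), grid$nlon)
    iy <- pmin(pmax(round(gi$gy), 1), grid$nlat)
    nodes <- unique(cbind(ix, iy))
    lev <- rep(level, nrow(nodes))
    vals <- numeric(0)
    for (k in seq_len(grid$n_snapshots)) {
      uu <- series$u[, , level, k][nodes]
      vv <- series$v[, , level, k][nodes]
      vals <- c(vals, sqrt(uu^2 + vv^2))
    }
    if (length(vals) == 0) stop("empty trajectory selection")
  }
  list(mean = mean(vals), max = max(vals))
}

#' Configuration of the synthetic sensitivity suite
#'
#' Problem sizes for the end-to-end suite on synthetic fields. The
#' defaults are scaled for interactive single-CPU use: a 20-day larval
#' duration, a handful of release times, and compressed "year" windows
#' for the saturation tests; the structure of every test (16 release
#' points per depth band at 700/1000/1500 m, the standard increment
#' lists, 10 km DST and 0.05 FUV thresholds) follows the standard
#' design. Scale `pld`, schedules and the domain up for
#' production-sized experiments.
#'
#' @param seed Master seed; each test derives its own substream.
#' @param depths Baseline depth bands (m) for TS/HS/RF/TR tests.
#' @param vs_depths Modified baselines for the VS test, chosen to sit in
#'   z-level bands of different vertical resolution.
#' @param n_points Release points per depth band.
#' @param pld Tracking duration (days).
#' @param timestep Baseline tracker timestep (s).
#' @param beach_tol_m Seafloor clearance tolerance of the beaching test
#'   (see [tracker_config()]).
#' @param clearance_m Seafloor clearance of the release rings (see
#'   [ring_release_points()]).
#' @param spatial_releases Number of release times for TS/HS/VS tests.
#' @param release_spacing Days between those release times.
#' @param rf_window Days in the release-frequency "year" window.
#' @param rf_counts Release counts tested against the daily baseline
#'   (baseline = one release per day of `rf_window`).
#' @param tr_years Number of "year" windows in the temporal-range test.
#' @param tr_year_length Days per window.
#' @param tr_releases Releases per window.
#' @param dst_threshold_km DST independence threshold (km).
#' @param fuv_threshold FUV saturation threshold.
#' @param half_width_deg Domain half-width (degrees).
#' @param raster_cell Density-raster cell size (degrees).
#' @param ts_increments,hs_increments,vs_increments Sweep increments
#'   (hours / degrees / metres).
#' @return An object of class `suite_config`.
#' @export
suite_config <- function(seed = 1L,
                         depths = c(700, 1000, 1500),
                         vs_depths = c(200, 1000, 1750),
                         n_points = 16,
                         pld = 45,
                         timestep = 10800,
                         beach_tol_m = 60,
                         clearance_m = 150,
                         spatial_releases = 2,
                         release_spacing = 10,
                         rf_window = 60,
                         rf_counts = c(30, 15, 9, 5, 2),
                         tr_years = 5,
                         tr_year_length = 30,
                         tr_releases = 4,
                         dst_threshold_km = 10,
                         fuv_threshold = 0.05,
                         half_width_deg = 3,
                         raster_cell = 0.04,
                         ts_increments = c(3, 6, 12, 24),
                         hs_increments = c(0.001, 0.005, 0.01, 0.025),
                         vs_increments = c(-0.1, -1, -10, -50)) {
  stopifnot(dst_threshold_km > 0, fuv_threshold > 0, pld >= 1)
  structure(as.list(environment()), class = "suite_config")
}

# Synthetic series for one test, sized to its schedule span.
.suite_series <- function(config, z_levels, span_days, seed_offset) {
  synthetic_series(z_levels = z_levels,
                   n_snapshots = ceiling(span_days) + 1,
                   seed = (config$seed + seed_offset) %% .Machine$integer.max,
                   half_width_deg = config$half_width_deg)
}

# Pool DST over pairs and fit the per-depth crossing for one spatial
# sweep. `runs` is a named list increment-value -> track_set aligned row
# by row with the baseline track_set. Pair-days after either member of
# a pair froze (beached or left the domain) are excluded from the pool:
# a frozen pair separates no further, and counting its repeated frozen
# distance would make the median measure the beaching rate rather than
# spatial autocorrelation.
.spatial_optima <- function(baseline_ts, runs, increments, depths,
                            threshold_km, baseline_value = 0,
                            depth_of = NULL) {
  if (is.null(depth_of)) depth_of <- baseline_ts$meta$depth
  res <- list(); summaries <- list()
  for (d in depths) {
    rows <- which(depth_of == d)
    med <- vapply(seq_along(increments), function(i) {
      dm <- .dst_matrix_pair(baseline_ts, runs[[i]], rows)
      live <- pmin(baseline_ts$meta$end_day[rows],
                   runs[[i]]$meta$end_day[rows])
      keep_days <- baseline_ts$days[baseline_ts$days >= 1]
      live_mask <- outer(live, keep_days, `>=`)   # rows x days, like dm
      vals <- dm[live_mask]
      if (length(vals) == 0) vals <- dm[, 1]
      stats::median(vals)
    }, numeric(1))
    summaries[[as.character(d)]] <-
      data.frame(depth = d, increment = increments, median_km = med)
    res[[as.character(d)]] <-
      sensitivity_curve(summaries[[as.character(d)]],
                        baseline = baseline_value,
                        threshold_km = threshold_km, depth = d)
  }
  list(curves = res, summaries = do.call(rbind, summaries))
}

# DST values between corresponding rows of two track sets.
.dst_matrix_pair <- function(a, b, rows) {
  keep <- which(a$days >= 1)
  haversine_km(a$lon[rows, keep], a$lat[rows, keep],
               b$lon[rows, keep], b$lat[rows, keep])
}

#' Run the full sensitivity suite on synthetic fields
#'
#' Executes the five parameter tests in the recommended order --
#' timestep first (so every later test runs at a validated timestep),
#' then release frequency, then horizontal and vertical separation,
#' then temporal range -- on synthetic eddy fields, and assembles the
#' optima table. Fully deterministic given `config$seed`.
#'
#' @param config A [suite_config()].
#' @param out_dir Optional directory for artifacts (summary CSVs, the
#'   optima table as CSV and Markdown, curve JSON).
#' @param tests Subset of tests to run (default all five).
#' @param quiet Suppress progress messages.
#' @return An object of class `optima_report`: data frame `optima` with
#'   one row per (parameter, depth), plus the per-test curves.
#' @export
run_sensitivity_suite <- function(config = suite_config(),
                                  out_dir = NULL,
                                  tests = c("TS", "RF", "HS", "VS", "TR"),
                                  quiet = FALSE) {
  tests <- match.arg(tests, c("TS", "RF", "HS", "VS", "TR"),
                     several.ok = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  curves <- list(); optima <- list(); errors <- list()
  add_rows <- function(parameter, test_type, fits) {
    do.call(rbind, lapply(names(fits), function(d)
      data.frame(parameter = parameter, test_type = test_type,
                 depth = as.numeric(d),
                 optimal = fits[[d]]$optimal,
                 extrapolated = isTRUE(fits[[d]]$extrapolated))))
  }
  run_guarded <- function(name, fn) {
    r <- tryCatch(fn(), error = function(e) e)
    if (inherits(r, "error")) {
      errors[[name]] <<- conditionMessage(r)
      say("%s test failed: %s", name, conditionMessage(r))
      NULL
    } else r
  }

  spatial_span <- (config$spatial_releases - 1) * config$release_spacing +
    config$pld

  if ("TS" %in% tests) {
    say("TS test (timestep sweep)...")
    r <- run_guarded("TS", function() {
      series <- .suite_series(config, config$depths, spatial_span, 101)
      sch <- data.frame(release_day =
        (seq_len(config$spatial_releases) - 1) * config$release_spacing)
      pts <- do.call(rbind, lapply(config$depths, function(d)
        ring_release_points(series$topo, d, config$n_points,
                            clearance_m = config$clearance_m)))
      pts$point_id <- pts$id
      rel <- pts[rep(seq_len(nrow(pts)), times = nrow(sch)), ]
      rel$release_day <- rep(sch$release_day, each = nrow(pts))
      cfg <- function(dt_h) tracker_config(timestep = dt_h * 3600,
                                           pld = config$pld,
                                           beach_tol_m = config$beach_tol_m)
      base <- run_release_set(series, rel, cfg(1))
      runs <- lapply(config$ts_increments, function(h)
        run_release_set(series, rel, cfg(h)))
      .spatial_optima(base, runs, config$ts_increments, config$depths,
                      config$dst_threshold_km, baseline_value = 1)
    })
    if (!is.null(r)) {
      curves$TS <- r$curves
      optima$TS <- add_rows("TS", "spatial autocorrelation", r$curves)
    }
  }

  if ("RF" %in% tests) {
    say("RF test (release frequency)...")
    r <- run_guarded("RF", function() {
      series <- .suite_series(config, config$depths,
                              config$rf_window + config$pld, 102)
      rspec <- raster_spec_for_grid(series$grid, config$raster_cell)
      sch <- build_release_schedule("daily", year_length = config$rf_window)
      fits <- list(); reps_all <- list()
      for (d in config$depths) {
        pts <- ring_release_points(series$topo, d, config$n_points,
                                   clearance_m = config$clearance_m)
        pts$point_id <- pts$id
        rel <- pts[rep(seq_len(nrow(pts)), times = nrow(sch)), ]
        rel$release_day <- rep(sch$release_day, each = nrow(pts))
        ts <- run_release_set(series, rel,
                              tracker_config(timestep = config$timestep,
                                             pld = config$pld,
                                             beach_tol_m = config$beach_tol_m))
        n_base <- nrow(sch)
        reps <- lapply(config$rf_counts, function(k) {
          sub_days <- build_release_schedule(
            k, year_length = config$rf_window)$release_day
          vapply(pts$point_id, function(p) {
            rows_b <- which(ts$meta$point_id == p)
            rows_i <- which(ts$meta$point_id == p &
                              ts$meta$release_day %in% sub_days)
            fuv(rasterize_tracks(ts[rows_b], rspec),
                rasterize_tracks(ts[rows_i], rspec))$fuv
          }, numeric(1))
        })
        env <- fuv_envelope(c(config$rf_counts, n_base),
                            c(reps, list(0)))
        fits[[as.character(d)]] <-
          optimal_from_envelope(env, config$fuv_threshold)
        fits[[as.character(d)]]$envelope <- env
        reps_all[[as.character(d)]] <- reps
      }
      list(fits = fits, replicates = reps_all)
    })
    if (!is.null(r)) {
      curves$RF <- r$fits
      optima$RF <- add_rows("RF", "model saturation", r$fits)
    }
  }

  if ("HS" %in% tests) {
    say("HS test (horizontal separation)...")
    r <- run_guarded("HS", function() {
      series <- .suite_series(config, config$depths, spatial_span, 103)
      design <- experiment_design(
        series$topo, depths = config$depths, n_points = config$n_points,
        schedule = local({
          s <- data.frame(release_day =
            (seq_len(config$spatial_releases) - 1) * config$release_spacing,
            year_index = 1L)
          class(s) <- c("release_schedule", "data.frame"); s
        }),
        sweep = parameter_sweep("HS", increments = config$hs_increments),
        clearance_m = config$clearance_m)
      rel <- design_release_table(design)
      ts <- run_release_set(series, rel,
                            tracker_config(timestep = config$timestep,
                                           pld = config$pld,
                                           beach_tol_m = config$beach_tol_m))
      base_rows <- ts$meta$role == "baseline"
      runs <- lapply(config$hs_increments, function(off) {
        sel <- which(ts$meta$increment == off)
        # order increment rows to match the baseline rows
        key_b <- paste(ts$meta$point_id[base_rows], ts$meta$depth[base_rows],
                       ts$meta$release_day[base_rows])
        key_i <- paste(ts$meta$point_id[sel], ts$meta$depth[sel],
                       ts$meta$release_day[sel])
        idx <- sel[match(key_b, key_i)]
        ts[idx]
      })
      base_ts <- ts[which(base_rows)]
      .spatial_optima(base_ts, runs, config$hs_increments, config$depths,
                      config$dst_threshold_km, baseline_value = 0)
    })
    if (!is.null(r)) {
      curves$HS <- r$curves
      optima$HS <- add_rows("HS", "spatial autocorrelation", r$curves)
    }
  }

  if ("VS" %in% tests) {
    say("VS test (vertical separation)...")
    r <- run_guarded("VS", function() {
      vs_levels <- sort(unique(unlist(lapply(config$vs_depths, function(d) {
        lv <- levitus_levels(150, 2000)
        lv[abs(lv - d) <= 260 | abs(lv - (d - 50)) <= 110]
      }))))
      series <- .suite_series(config, vs_levels, spatial_span, 104)
      topo <- series$topo
      sch_days <- (seq_len(config$spatial_releases) - 1) *
        config$release_spacing
      rel <- NULL
      for (d in config$vs_depths) {
        # releases shallower than the summit sit in the water column
        # above the summit plateau edge
        contour_depth <- max(d, topo$summit_depth + 25)
        pts <- ring_release_points(topo, contour_depth, config$n_points,
                                   clearance_m = config$clearance_m)
        pts$depth <- d
        pts$point_id <- pts$id
        pts$depth_band <- d
        all <- pts
        for (dz in config$vs_increments) {
          inc <- pts
          inc$depth <- pts$depth - abs(dz)
          inc$role <- "increment"
          inc$increment <- -abs(dz)
          all <- rbind(all, inc)
        }
        for (day in sch_days) {
          a <- all; a$release_day <- day
          rel <- rbind(rel, a)
        }
      }
      ts <- run_release_set(series, rel,
                            tracker_config(timestep = config$timestep,
                                           pld = config$pld,
                                           beach_tol_m = config$beach_tol_m))
      base_rows <- ts$meta$role == "baseline"
      runs <- lapply(config$vs_increments, function(dz) {
        sel <- which(ts$meta$increment == -abs(dz))
        key_b <- paste(ts$meta$point_id[base_rows],
                       ts$meta$depth_band[base_rows],
                       ts$meta$release_day[base_rows])
        key_i <- paste(ts$meta$point_id[sel], ts$meta$depth_band[sel],
                       ts$meta$release_day[sel])
        ts[sel[match(key_b, key_i)]]
      })
      base_ts <- ts[which(base_rows)]
      .spatial_optima(base_ts, runs, abs(config$vs_increments),
                      config$vs_depths, config$dst_threshold_km,
                      baseline_value = 0,
                      depth_of = base_ts$meta$depth_band)
    })
    if (!is.null(r)) {
      curves$VS <- r$curves
      optima$VS <- add_rows("VS", "spatial autocorrelation", r$curves)
    }
  }

  if ("TR" %in% tests) {
    say("TR test (temporal range)...")
    r <- run_guarded("TR", function() {
      span <- config$tr_years * config$tr_year_length + config$pld
      series <- .suite_series(config, config$depths, span, 105)
      rspec <- raster_spec_for_grid(series$grid, config$raster_cell)
      sch <- build_release_schedule(config$tr_releases,
                                    n_years = config$tr_years,
                                    year_length = config$tr_year_length)
      fits <- list()
      for (d in config$depths) {
        pts <- ring_release_points(series$topo, d, config$n_points,
                                   clearance_m = config$clearance_m)
        pts$point_id <- pts$id
        rel <- pts[rep(seq_len(nrow(pts)), times = nrow(sch)), ]
        rel$release_day <- rep(sch$release_day, each = nrow(pts))
        rel$year_index <- rep(sch$year_index, each = nrow(pts))
        ts <- run_release_set(series, rel,
                              tracker_config(timestep = config$timestep,
                                             pld = config$pld,
                                             beach_tol_m = config$beach_tol_m))
        ks <- seq_len(config$tr_years - 1)
        reps <- lapply(ks, function(k) {
          subsets <- year_combinations(seq_len(config$tr_years), k)
          unlist(lapply(pts$point_id, function(p) {
            rows_b <- which(ts$meta$point_id == p)
            base_r <- rasterize_tracks(ts[rows_b], rspec)
            vapply(subsets, function(su) {
              rows_i <- which(ts$meta$point_id == p &
                                ts$meta$year_index %in% su$years)
              fuv(base_r, rasterize_tracks(ts[rows_i], rspec))$fuv
            }, numeric(1))
          }))
        })
        env <- fuv_envelope(c(ks, config$tr_years), c(reps, list(0)))
        fits[[as.character(d)]] <-
          optimal_from_envelope(env, config$fuv_threshold)
        fits[[as.character(d)]]$envelope <- env
      }
      list(fits = fits)
    })
    if (!is.null(r)) {
      curves$TR <- r$fits
      optima$TR <- add_rows("TR", "model saturation", r$fits)
    }
  }

  report <- structure(list(
    optima = do.call(rbind, optima),
    curves = curves,
    errors = errors,
    config = config), class = "optima_report")
  rownames(report$optima) <- NULL
  if (!is.null(out_dir)) write_optima_report(report, out_dir)
  report
}

#' @export
print.optima_report <- function(x, ...) {
  cat("<optima_report>\n")
  df <- x$optima
  df$optimal <- signif(df$optimal, 3)
  df$flag <- ifelse(df$extrapolated, "(approx.)", "")
  print(df[, c("parameter", "test_type", "depth", "optimal", "flag")],
        row.names = FALSE)
  if (length(x$errors))
    cat("failed tests:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Persist an optima report
#'
#' Writes the optima table as CSV and as a Markdown table, and the
#' fitted curves as JSON.
#'
#' @param report An `optima_report`.
#' @param out_dir Output directory (created if missing).
#' @export
write_optima_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$optima, file.path(out_dir, "optima.csv"),
                   row.names = FALSE)
  md <- c("| Parameter | Test type | Depth (m) | Optimal value |",
          "|---|---|---|---|",
          sprintf("| %s | %s | %g | %s%s |",
                  report$optima$parameter, report$optima$test_type,
                  report$optima$depth,
                  signif(report$optima$optimal, 3),
                  ifelse(report$optima$extrapolated, " (approx.)", "")))
  writeLines(md, file.path(out_dir, "optima.md"))
  ser <- lapply(report$curves, function(tst)
    lapply(tst, function(cv) {
      if (inherits(cv, "sensitivity_curve"))
        list(depth = cv$depth, knots = cv$knots, threshold = cv$threshold,
             optimal = cv$optimal, extrapolated = cv$extrapolated)
      else
        list(envelope = cv$envelope, optimal = cv$optimal,
             extrapolated = cv$extrapolated)
    }))
  jsonlite::write_json(ser, file.path(out_dir, "curves.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
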