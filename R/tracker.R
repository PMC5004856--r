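# Passive 2-D Lagrangian tracker: classical fourth-order Runge-Kutta
# advection in degree space with per-stage metric conversion, at fixed
# depth horizons (no vertical motion). Particles that leave the grid are
# flagged "escaped"; particles whose position ends up over seafloor
# shallower than their depth are flagged "beached". Both are frozen at
# the last valid position, which keeps replicate designs balanced for
# the DST and FUV analyses.

#' Tracker configuration
#'
#' @param timestep Integration timestep in seconds (default 3600 = 1 h,
#'   the baseline setting of the timestep sensitivity test). Must divide
#'   `output_interval` days exactly.
#' @param pld Planktonic larval duration in days: the tracking time
#'   (default 100, covering ~90% of known deep-sea larval durations).
#' @param output_interval Days between recorded positions (default 1).
#' @param mode Horizontal interpolation: `"cubic"` (default) or
#'   `"linear"`.
#' @param beach_tol_m Vertical clearance tolerance (m) of the beaching
#'   test: a particle is beached when the interpolated seafloor is more
#'   than this much shallower than its depth. The default 25 m treats
#'   the near-bottom layer as navigable, so particles riding the
#'   boundary streamline of a seamount are not terminated by numerical
#'   wobble.
#' @param radius_km Earth radius (km) for the metric conversion.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(timestep = 3600, pld = 100,
                           output_interval = 1,
                           mode = c("cubic", "linear"),
                           beach_tol_m = 25,
                           radius_km = EARTH_RADIUS_KM) {
  mode <- match.arg(mode)
  stopifnot(timestep > 0, pld >= 1, output_interval > 0)
  steps <- output_interval * 86400 / timestep
  if (abs(steps - round(steps)) > 1e-9)
    stop("timestep must divide output_interval * 86400 seconds")
  structure(list(timestep = timestep, pld = pld,
                 output_interval = output_interval, mode = mode,
                 beach_tol_m = beach_tol_m, radius_km = radius_km,
                 steps_per_output = as.integer(round(steps))),
            class = "tracker_config")
}

# Seafloor clearance test: TRUE where the particle is in the water
# column (bilinear seafloor depth >= particle depth - tolerance).
.in_water <- function(series, lon, lat, depth, tol = 25) {
  if (is.null(series$topo)) return(rep(TRUE, length(lon)))
  sf <- topo_depth_at(series$topo, lon, lat)
  !is.na(sf) & sf >= depth - tol
}

# Vectorised RK4 step for a batch of particles. lon/lat/depth vectors,
# time in days (scalar), dt in seconds. Returns new positions plus
# per-particle failure flags: oob (left grid / time span during any
# stage) and land (any stage over too-shallow seafloor).
.rk4_batch <- function(series, lon, lat, depth, time_days, dt, config) {
  mlat <- m_per_deg_lat(config$radius_km)
  day <- 86400
  n <- length(lon)
  oob <- rep(FALSE, n); land <- rep(FALSE, n)
  deriv <- function(lo, la, tday) {
    s <- .sample_uv(series, lo, la, depth, tday, config$mode)
    oob <<- oob | s$oob
    land <<- land | !.in_water(series, lo, la, depth, config$beach_tol_m)
    u <- ifelse(is.na(s$u), 0, s$u); v <- ifelse(is.na(s$v), 0, s$v)
    list(dlon = u / (mlat * cos(la * pi / 180)) * day,  # deg/day
         dlat = v / mlat * day)
  }
  h <- dt / day                                         # days
  k1 <- deriv(lon, lat, time_days)
  k2 <- deriv(lon + h / 2 * k1$dlon, lat + h / 2 * k1$dlat, time_days + h / 2)
  k3 <- deriv(lon + h / 2 * k2$dlon, lat + h / 2 * k2$dlat, time_days + h / 2)
  k4 <- deriv(lon + h * k3$dlon, lat + h * k3$dlat, time_days + h)
  nlon <- lon + h / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon)
  nlat_ <- lat + h / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
  # the landing position itself must also be valid
  oob <- oob | !.in_bounds(series$grid, nlon, nlat_)
  land <- land | !ifelse(oob, TRUE,
                         .in_water(series, nlon, nlat_, depth,
                                   config$beach_tol_m))
  list(lon = nlon, lat = nlat_, oob = oob, land = land & !oob)
}

#' Single fourth-order Runge-Kutta advection step
#'
#' Advances one particle state by `dt` seconds through the velocity
#' series: classical RK4 on d(lon)/dt = u / (m_deg_lat * cos(lat)),
#' d(lat)/dt = v / m_deg_lat, each stage re-sampling the velocity at its
#' own position and time. Depth is unchanged. A stage leaving the grid
#' marks the particle `escaped`; a stage over too-shallow seafloor marks
#' it `beached`; in both cases the state is frozen at the pre-step
#' position.
#'
#' @param series A `velocity_field_series`.
#' @param state List with `lon`, `lat`, `depth` (m), `time` (seconds
#'   since the series origin) and `status`.
#' @param dt Timestep in seconds.
#' @param config A [tracker_config()] (interpolation mode, radius).
#' @return The updated state.
#' @export
rk4_step <- function(series, state, dt, config = tracker_config()) {
  stopifnot(dt > 0)
  if (!identical(state$status, "active"))
    stop("particle is not active")
  r <- .rk4_batch(series, state$lon, state$lat, state$depth,
                  state$time / 86400, dt, config)
  if (r$oob) {
    state$status <- "escaped"
  } else if (r$land) {
    state$status <- "beached"
  } else {
    state$lon <- r$lon; state$lat <- r$lat
  }
  state$time <- state$time + dt
  state
}

#' Advect one particle and record its daily track
#'
#' Integrates a release through the field series for `config$pld` days,
#' recording the position every `config$output_interval` days (the
#' release position is the day-0 record). If the particle beaches or
#' escapes, its position freezes there and the remaining records repeat
#' the frozen position, so every track has `pld / output_interval + 1`
#' records regardless of fate.
#'
#' @param series A `velocity_field_series`.
#' @param release List or one-row data frame with `lon`, `lat`, `depth`.
#' @param release_time Release time in days since the series origin.
#' @param config A [tracker_config()].
#' @return An object of class `disp_track`: `lon`, `lat`, `day` vectors,
#'   `depth`, `status`, `release_time`.
#' @export
advect_particle <- function(series, release, release_time = 0,
                            config = tracker_config()) {
  rel <- data.frame(id = if (!is.null(release$id)) release$id else 1L,
                    lon = release$lon, lat = release$lat,
                    depth = release$depth, release_day = release_time)
  ts <- run_release_set(series, rel, config)
  track <- ts[1L]
  track
}

#' Run a whole set of releases through the tracker
#'
#' The batch engine: every release (one row per particle) is advected on
#' a shared global clock, so particles released at different times run
#' in one pass. Releases must be inside the grid and in the water
#' column, and their tracking windows must fit the field series span.
#'
#' @param series A `velocity_field_series`.
#' @param releases Data frame with columns `lon`, `lat`, `depth`,
#'   `release_day` (days since the series origin; whole multiples of
#'   `config$output_interval`) and optional metadata columns (`id`,
#'   `point_id`, `role`, `increment`, ...), carried through.
#' @param config A [tracker_config()].
#' @return An object of class `track_set`: metadata data frame plus
#'   `lon`/`lat` matrices of dim (n_tracks, pld/output_interval + 1) and
#'   the `days` vector.
#' @export
run_release_set <- function(series, releases, config = tracker_config()) {
  n <- nrow(releases)
  days <- seq(0, config$pld, by = config$output_interval)
  nrec <- length(days)
  meta <- releases
  if (is.null(meta$id)) meta$id <- seq_len(n)
  if (is.null(meta$release_day)) meta$release_day <- 0
  meta$status <- rep("active", n)
  if (n == 0L)
    return(structure(list(meta = meta,
                          lon = matrix(numeric(0), 0, nrec),
                          lat = matrix(numeric(0), 0, nrec),
                          days = days, config = config),
                     class = "track_set"))

  span <- series$grid$snapshot_days[series$grid$n_snapshots]
  if (any(meta$release_day < 0 | meta$release_day + config$pld > span + 1e-9))
    stop("release windows exceed the field series time span")
  rel_steps <- meta$release_day * 86400 / config$timestep
  if (any(abs(rel_steps - round(rel_steps)) > 1e-6))
    stop("release days must align with the integration timestep")
  ok0 <- .in_bounds(series$grid, meta$lon, meta$lat) &
    .in_water(series, meta$lon, meta$lat, meta$depth, config$beach_tol_m)
  if (!all(ok0))
    stop("release point(s) on land / inside the seamount: ",
         paste(utils::head(which(!ok0), 5), collapse = ", "))

  lonM <- matrix(NA_real_, n, nrec)
  latM <- matrix(NA_real_, n, nrec)
  lonM[, 1] <- meta$lon; latM[, 1] <- meta$lat
  lon <- meta$lon; lat <- meta$lat
  status <- rep("active", n)
  end_day <- rep(config$pld, n)   # day (since release) the track froze

  dt_days <- config$timestep / 86400
  t0 <- min(meta$release_day)
  t_end <- max(meta$release_day) + config$pld
  nstep <- as.integer(round((t_end - t0) / dt_days))
  rec_of <- function(t) {
    # record slot (1-based) for each particle at global day t, NA if none
    k <- (t - meta$release_day) / config$output_interval
    k[k < 0 | k > (nrec - 1) | abs(k - round(k)) > 1e-6] <- NA
    as.integer(round(k)) + 1L
  }
  for (s in seq_len(nstep)) {
    t_now <- t0 + (s - 1L) * dt_days
    act <- which(status == "active" &
                   meta$release_day <= t_now + 1e-9 &
                   meta$release_day + config$pld > t_now + 1e-9)
    if (length(act)) {
      r <- .rk4_batch(series, lon[act], lat[act],
                      meta$depth[act], t_now, config$timestep, config)
      move <- !(r$oob | r$land)
      lon[act[move]] <- r$lon[move]
      lat[act[move]] <- r$lat[move]
      status[act[r$oob]] <- "escaped"
      status[act[r$land]] <- "beached"
      froze <- act[r$oob | r$land]
      end_day[froze] <- floor(t_now - meta$release_day[froze] + 1e-9)
    }
    t_next <- t0 + s * dt_days
    slot <- rec_of(t_next)
    rec <- which(!is.na(slot))
    if (length(rec)) {
      idx <- cbind(rec, slot[rec])
      lonM[idx] <- lon[rec]
      latM[idx] <- lat[rec]
    }
  }
  meta$status <- status
  meta$end_day <- end_day
  structure(list(meta = meta, lon = lonM, lat = latM, days = days,
                 config = config),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks x %d daily records; status: %s\n",
              nrow(x$meta), length(x$days),
              paste(names(table(x$meta$status)), table(x$meta$status),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
`[.track_set` <- function(x, i) {
  m <- x$meta[i, , drop = FALSE]
  if (nrow(m) == 1L) {
    structure(list(id = m$id, lon = x$lon[i, ], lat = x$lat[i, ],
                   day = x$days, depth = m$depth, status = m$status,
                   release_time = m$release_day, meta = m),
              class = "disp_track")
  } else {
    structure(list(meta = m, lon = x$lon[i, , drop = FALSE],
                   lat = x$lat[i, , drop = FALSE], days = x$days,
                   config = x$config),
              class = "track_set")
  }
}

#' @export
print.disp_track <- function(x, ...) {
  cat(sprintf("<disp_track> %d daily positions at %g m, status %s\n",
              length(x$day), x$depth, x$status))
  invisible(x)
}

#' @export
as.data.frame.track_set <- function(x, ...) {
  n <- nrow(x$meta); nrec <- length(x$days)
  out <- data.frame(
    track_id = rep(x$meta$id, each = nrec),
    depth = rep(x$meta$depth, each = nrec),
    release_day = rep(x$meta$release_day, each = nrec),
    day = rep(x$days, n),
    lon = as.vector(t(x$lon)),
    lat = as.vector(t(x$lat)),
    status = rep(x$meta$status, each = nrec))
  if (!is.null(x$meta$role)) out$role <- rep(x$meta$role, each = nrec)
  if (!is.null(x$meta$increment))
    out$increment <- rep(x$meta$increment, each = nrec)
  out
}

#' Write a track set to CSV
#'
#' Long-format trajectory export: one row per (track, day).
#'
#' @param x A `track_set`.
#' @param path Output CSV path.
#' @export
write_tracks_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
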