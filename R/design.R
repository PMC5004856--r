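# Experiment-design builders: ring release points on a seamount depth
# contour, horizontal/vertical increment placement, release schedules,
# year combinations, parameter sweeps, and exact enumeration of the
# particle counts a design implies.

.contour_cache <- new.env(parent = emptyenv())

# Extract the closed contour of `topo` at depth (metres) as a polygon
# with cumulative arc length (km). The raw contour polygon is densified
# (4 points per segment) and every vertex is snapped radially onto the
# interpolated depth surface, so points taken anywhere along the
# polyline sit on the contour to well under a metre of seafloor depth.
# Errors when no closed contour exists. Results are cached.
.depth_contour <- function(topo, depth) {
  grid <- topo$grid
  key <- sprintf("%.17g|%.17g|%d|%d|%.17g|%.17g", depth,
                 sum(topo$depth), nrow(topo$depth), ncol(topo$depth),
                 grid$lon_min, grid$lat_min)
  if (!is.null(.contour_cache[[key]])) return(.contour_cache[[key]])
  cl <- grDevices::contourLines(grid$lon, grid$lat, topo$depth,
                                levels = depth)
  closed <- Filter(function(c) {
    length(c$x) > 3 &&
      abs(c$x[1] - c$x[length(c$x)]) < 1e-9 &&
      abs(c$y[1] - c$y[length(c$y)]) < 1e-9
  }, cl)
  if (length(closed) == 0)
    stop("no closed contour at depth ", depth, " m")
  # largest closed contour by vertex count
  cc <- closed[[which.max(vapply(closed, function(c) length(c$x),
                                 numeric(1)))]]
  x <- cc$x; y <- cc$y
  # circle centre: refine the vertex centroid by minimising the variance
  # of great-circle distances to the vertices (the lon/lat centroid of a
  # spherical circle is biased poleward)
  vx <- x[-length(x)]; vy <- y[-length(y)]
  c0 <- c(mean(vx), mean(vy))
  ctr <- stats::optim(c0, function(p)
    stats::var(haversine_km(vx, vy, p[1], p[2])),
    method = "Nelder-Mead",
    control = list(reltol = 1e-14))$par
  # densify segments, then snap every vertex radially onto the depth
  # surface by a few secant iterations on the scale factor about centre
  m <- length(x) - 1L
  tfrac <- seq(0, 0.75, by = 0.25)
  xd <- as.vector(vapply(seq_len(m), function(i)
    x[i] + tfrac * (x[i + 1] - x[i]), numeric(4)))
  yd <- as.vector(vapply(seq_len(m), function(i)
    y[i] + tfrac * (y[i + 1] - y[i]), numeric(4)))
  sc <- rep(1, length(xd))
  px <- function(s) ctr[1] + s * (xd - ctr[1])
  py <- function(s) ctr[2] + s * (yd - ctr[2])
  for (it in 1:6) {
    d0 <- topo_depth_at(topo, px(sc), py(sc))
    d1 <- topo_depth_at(topo, px(sc * 1.001), py(sc * 1.001))
    slope <- (d1 - d0) / (sc * 0.001)
    upd <- is.finite(slope) & abs(slope) > 1e-6
    sc[upd] <- sc[upd] + (depth - d0[upd]) / slope[upd]
    sc <- pmin(pmax(sc, 0.5), 1.5)
  }
  keep <- is.finite(topo_depth_at(topo, px(sc), py(sc)))
  xs <- c(px(sc)[keep], px(sc)[keep][1])
  ys <- c(py(sc)[keep], py(sc)[keep][1])
  seg <- haversine_km(xs[-length(xs)], ys[-length(ys)], xs[-1], ys[-1])
  out <- list(lon = xs, lat = ys, s = c(0, cumsum(seg)),
              length_km = sum(seg),
              centroid = c(lon = ctr[1], lat = ctr[2]))
  .contour_cache[[key]] <- out
  out
}

# Point on the contour polyline at arc length s (km), wrapping around.
.contour_point_at <- function(ct, s) {
  s <- s %% ct$length_km
  i <- findInterval(s, ct$s, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(ct$s) - 1L)
  w <- (s - ct$s[i]) / (ct$s[i + 1] - ct$s[i])
  list(lon = ct$lon[i] + w * (ct$lon[i + 1] - ct$lon[i]),
       lat = ct$lat[i] + w * (ct$lat[i + 1] - ct$lat[i]))
}

# Arc-length position (km) of the contour vertex/edge point nearest to
# (lon, lat): projection onto the closest segment.
.contour_arc_of <- function(ct, lon, lat) {
  n <- length(ct$lon)
  ax <- ct$lon[-n]; ay <- ct$lat[-n]
  bx <- ct$lon[-1]; by <- ct$lat[-1]
  # planar projection in degree space is adequate at contour scale
  vx <- bx - ax; vy <- by - ay
  t <- ((lon - ax) * vx + (lat - ay) * vy) / (vx^2 + vy^2)
  t <- pmin(pmax(t, 0), 1)
  px <- ax + t * vx; py <- ay + t * vy
  d2 <- (px - lon)^2 + (py - lat)^2
  i <- which.min(d2)
  ct$s[i] + t[i] * (ct$s[i + 1] - ct$s[i])
}

#' Release points on a seamount depth contour
#'
#' Places `n` release points on the closed contour of the seafloor at
#' the requested depth, at equal angular spacing about the contour
#' centroid; ids run `0..n-1` clockwise from north. Points sit exactly
#' on the depth contour, simulating the release of benthic larvae at
#' the seamount interface.
#'
#' @param topo A [guyot_topography()] (or any `topography` with a closed
#'   contour at `depth`).
#' @param depth Contour depth (m), also assigned as the points' release
#'   depth.
#' @param n Number of points (default 16).
#' @param clearance_m Seafloor clearance (m) of the placed points: they
#'   are snapped to the contour of `depth + clearance_m` while keeping
#'   the release depth at `depth`. The default 100 m is about half the
#'   radial depth change per grid cell on a typical flank, mirroring
#'   release sites at the centre of the last water cell that interfaces
#'   the seamount rather than on the unresolvable sub-grid interface
#'   line itself.
#' @return Data frame with `id`, `lon`, `lat`, `depth`, `role`
#'   (`"baseline"`), `increment` (0).
#' @export
ring_release_points <- function(topo, depth, n = 16, clearance_m = 100) {
  stopifnot(n >= 1, clearance_m >= 0)
  ct <- .depth_contour(topo, depth + clearance_m)
  cx <- ct$centroid["lon"]; cy <- ct$centroid["lat"]
  # great-circle initial bearing (degrees clockwise from north) from the
  # centroid to each contour vertex: equal bearing spacing around a
  # circular contour gives equal great-circle point spacing
  rad <- pi / 180
  dlam <- (ct$lon - cx) * rad
  phi1 <- cy * rad; phi2 <- ct$lat * rad
  brg <- (atan2(sin(dlam) * cos(phi2),
                cos(phi1) * sin(phi2) -
                  sin(phi1) * cos(phi2) * cos(dlam)) / rad) %% 360
  targets <- (seq_len(n) - 1L) * 360 / n
  pts <- lapply(targets, function(b) {
    # signed angular difference, then the vertex pair straddling b
    # (works for either traversal orientation of the contour polygon)
    d <- ((brg - b + 180) %% 360) - 180
    m <- length(d) - 1L                    # last vertex repeats the first
    dj <- d[seq_len(m)]; dj2 <- d[c(2:m, 1)]
    j <- which(dj * dj2 <= 0 & abs(dj) < 90 & abs(dj2) < 90)
    if (length(j) == 0) {
      j <- which.min(abs(dj)); w <- 0
    } else {
      j <- j[which.min(abs(dj[j]))]
      w <- if (abs(dj2[j] - dj[j]) < 1e-12) 0 else dj[j] / (dj[j] - dj2[j])
    }
    j2 <- if (j == m) 1L else j + 1L
    list(lon = ct$lon[j] + w * (ct$lon[j2] - ct$lon[j]),
         lat = ct$lat[j] + w * (ct$lat[j2] - ct$lat[j]))
  })
  # refine radially: the polygonal contour chords sit slightly inside the
  # true contour, so snap each point to the interpolated depth along the
  # ray from the centroid
  pts <- lapply(pts, function(p) {
    f <- function(s) topo_depth_at(topo,
                                   cx + s * (p$lon - cx),
                                   cy + s * (p$lat - cy)) -
      (depth + clearance_m)
    root <- tryCatch(stats::uniroot(f, c(0.85, 1.15), tol = 1e-10)$root,
                     error = function(e) 1)
    list(lon = cx + root * (p$lon - cx), lat = cy + root * (p$lat - cy))
  })
  data.frame(id = seq_len(n) - 1L,
             lon = vapply(pts, `[[`, numeric(1), "lon"),
             lat = vapply(pts, `[[`, numeric(1), "lat"),
             depth = depth, contour_depth = depth + clearance_m,
             role = "baseline", increment = 0)
}

#' Offset a release point along its depth contour
#'
#' Moves a point clockwise along the seamount contour by an arc length
#' equivalent to `offset_deg` degrees (buffer-radius-in-degrees
#' semantics: arc = offset * pi/180 * R = offset * 111.195 km), keeping
#' the same depth. This reproduces, deterministically, the GIS
#' buffer-then-snap-to-contour placement of horizontal-separation
#' increments.
#'
#' @param point One-row data frame (or list) with `lon`, `lat`, `depth`.
#' @param offset_deg Offset in degrees (> 0).
#' @param topo The topography carrying the contour.
#' @return The offset point as a one-row data frame with `role =
#'   "increment"` and the offset recorded in `increment`.
#' @export
offset_along_contour <- function(point, offset_deg, topo) {
  stopifnot(offset_deg > 0)
  cdepth <- if (!is.null(point$contour_depth)) point$contour_depth
            else point$depth
  ct <- .depth_contour(topo, cdepth)
  arc <- offset_deg * pi / 180 * EARTH_RADIUS_KM
  if (arc > ct$length_km / 2)
    stop("offset exceeds half the contour length")
  s0 <- .contour_arc_of(ct, point$lon, point$lat)
  # clockwise = direction of decreasing bearing-parametrised arc; use the
  # polygon's own orientation, negating when it runs anticlockwise
  p <- .contour_point_at(ct, s0 + arc * .contour_orientation(ct))
  data.frame(id = if (!is.null(point$id)) point$id else NA_integer_,
             lon = p$lon, lat = p$lat, depth = point$depth,
             contour_depth = cdepth,
             role = "increment", increment = offset_deg)
}

# +1 when the contour polygon is ordered clockwise (viewed with north
# up), -1 otherwise (shoelace sign in lon/lat space).
.contour_orientation <- function(ct) {
  n <- length(ct$lon)
  a <- sum(ct$lon[-n] * ct$lat[-1] - ct$lon[-1] * ct$lat[-n])
  if (a < 0) 1 else -1
}

#' Offset a release point vertically
#'
#' Shifts the release depth shallower by `|dz|` metres, keeping lon/lat
#' fixed: the vertical-separation increments are pure depth
#' displacements towards the surface.
#'
#' @param point One-row data frame (or list) with `lon`, `lat`, `depth`.
#' @param dz Vertical increment in metres; its magnitude is subtracted
#'   from the depth (increments are conventionally quoted negative).
#' @return The shifted point, `role = "increment"`, `increment = -|dz|`.
#' @export
offset_depth <- function(point, dz) {
  nd <- point$depth - abs(dz)
  if (nd <= 0) stop("vertical offset would place the point above the surface")
  out <- data.frame(id = if (!is.null(point$id)) point$id else NA_integer_,
             lon = point$lon, lat = point$lat, depth = nd,
             role = if (dz == 0) "baseline" else "increment",
             increment = -abs(dz))
  if (!is.null(point$contour_depth)) out$contour_depth <- point$contour_depth
  out
}

#' Parameter sweep definition
#'
#' Baseline and increment list for one of the five tested parameters,
#' with defaults matching the standard test table: timestep increments
#' 3/6/12/24 h against a 1 h baseline; horizontal separations
#' +0.001/0.005/0.01/0.025 degrees; vertical separations -0.1/-1/-10/-50 m;
#' release frequencies 183/104/52/12/4 per year against a daily (365)
#' baseline; temporal ranges 1-4 years against a 5-year baseline.
#'
#' @param parameter One of `"TS"`, `"HS"`, `"VS"`, `"RF"`, `"TR"`.
#' @param baseline,increments Optional overrides of the defaults.
#' @return An object of class `parameter_sweep`.
#' @export
parameter_sweep <- function(parameter = c("TS", "HS", "VS", "RF", "TR"),
                            baseline = NULL, increments = NULL) {
  parameter <- match.arg(parameter)
  defaults <- list(
    TS = list(baseline = 1, increments = c(3, 6, 12, 24)),        # hours
    HS = list(baseline = 0, increments = c(0.001, 0.005, 0.01, 0.025)),
    VS = list(baseline = 0, increments = c(-0.1, -1, -10, -50)),  # metres
    RF = list(baseline = 365, increments = c(183, 104, 52, 12, 4)),
    TR = list(baseline = 5, increments = c(1, 2, 3, 4)))          # years
  d <- defaults[[parameter]]
  if (is.null(baseline)) baseline <- d$baseline
  if (is.null(increments)) increments <- d$increments
  if (anyDuplicated(increments)) stop("increments must be distinct")
  structure(list(parameter = parameter, baseline = baseline,
                 increments = increments),
            class = "parameter_sweep")
}

#' Build a release schedule
#'
#' Evenly spaced release days over one or more "years" (windows of
#' `year_length` days). The standard frequency labels give the counts
#' daily = 365, `2-daily` = 183, biweekly (twice weekly) = 104,
#' weekly = 52, monthly = 12, seasonal = 4 per year; an explicit integer
#' count may be given instead. Release times snap to whole days (the
#' driving fields are daily averages, so sub-day phases carry no
#' information); counts are preserved exactly, including 365 releases in
#' leap years.
#'
#' @param frequency A label (`"daily"`, `"2-daily"`, `"biweekly"`,
#'   `"weekly"`, `"monthly"`, `"seasonal"`) or a positive integer count
#'   per year.
#' @param n_years Number of consecutive year-windows (default 1).
#' @param start_day First release day (days since the field-series
#'   origin).
#' @param year_length Days per year-window (default 365; shrink for
#'   scaled synthetic experiments).
#' @return An object of class `release_schedule`: data frame with
#'   `release_day`, `year_index`, plus attributes `frequency` and
#'   `per_year`.
#' @export
build_release_schedule <- function(frequency, n_years = 1, start_day = 0,
                                   year_length = 365) {
  labels <- c(daily = 365, `2-daily` = 183, biweekly = 104,
              weekly = 52, monthly = 12, seasonal = 4)
  if (is.character(frequency)) {
    if (!frequency %in% names(labels))
      stop("unknown release frequency label '", frequency, "'")
    n <- labels[[frequency]]
    label <- frequency
    # labels are counts per 365-day year; scale them to the window
    if (year_length != 365)
      n <- max(1L, as.integer(round(n * year_length / 365)))
  } else {
    n <- as.integer(frequency)
    if (is.na(n) || n < 1) stop("release count must be a positive integer")
    label <- paste0(n, "/window")
  }
  within <- floor((seq_len(n) - 1L) * year_length / n)
  if (anyDuplicated(within))
    stop("release frequency too high for daily snapping in this window")
  days <- as.vector(outer(within, (seq_len(n_years) - 1L) * year_length, `+`))
  out <- data.frame(release_day = start_day + days,
                    year_index = rep(seq_len(n_years), each = n))
  attr(out, "frequency") <- label
  attr(out, "per_year") <- n
  class(out) <- c("release_schedule", "data.frame")
  out
}

#' All k-year subsets of a set of years
#'
#' Enumerates, in lexicographic order, every combination of `k` years
#' out of the supplied years, optionally tagging each with climate-state
#' labels (e.g. North Atlantic Oscillation states) per year.
#'
#' @param years Vector of year labels.
#' @param k Subset size, `1 <= k <= length(years)`.
#' @param states Optional named vector mapping year label to state tag.
#' @return List of subsets; each element has `years` and `states`.
#' @export
year_combinations <- function(years, k, states = NULL) {
  if (k < 1 || k > length(years)) stop("k out of range")
  cmb <- utils::combn(seq_along(years), k, simplify = FALSE)
  lapply(cmb, function(idx) {
    ys <- years[idx]
    list(years = ys,
         states = if (is.null(states)) rep(NA_character_, k)
                  else unname(states[as.character(ys)]))
  })
}

#' Winter NAO state tags used for year labelling
#'
#' December-March mean North Atlantic Oscillation states for the
#' simulated years: 2009 neutral, 2010 strongly negative, 2012 strongly
#' positive (the three-year "climate extremes" subset); other years
#' unclassified.
#'
#' @return Named character vector keyed by year.
#' @export
nao_states <- function() {
  c(`2008` = "other", `2009` = "neutral", `2010` = "strong negative",
    `2011` = "other", `2012` = "strong positive", `2013` = "other")
}

#' Full experiment design for one parameter sweep
#'
#' Combines ring release points per depth, a release schedule and a
#' parameter sweep into an enumerable design. For HS and VS sweeps the
#' increments materialise as additional release points (offset along the
#' contour / in depth); for TS the increments are tracker timesteps; for
#' RF/TR they are alternative schedules.
#'
#' @param topo Topography used for point placement.
#' @param depths Baseline depth bands (m); default 700/1000/1500.
#' @param n_points Release points per depth band (default 16).
#' @param schedule A [build_release_schedule()].
#' @param sweep A [parameter_sweep()].
#' @param clearance_m Seafloor clearance of the release ring; see
#'   [ring_release_points()].
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(topo, depths = c(700, 1000, 1500),
                              n_points = 16,
                              schedule = build_release_schedule("monthly"),
                              sweep = parameter_sweep("HS"),
                              clearance_m = 100) {
  points <- do.call(rbind, lapply(depths, function(d)
    ring_release_points(topo, d, n_points, clearance_m = clearance_m)))
  structure(list(topo = topo, depths = depths, n_points = n_points,
                 points = points, schedule = schedule, sweep = sweep),
            class = "experiment_design")
}

#' Release table implied by a design
#'
#' Expands an [experiment_design()] into one row per particle: baseline
#' points and, for HS/VS sweeps, every increment point, crossed with the
#' release schedule.
#'
#' @param design An `experiment_design`.
#' @return Data frame with `id`, `point_id`, `lon`, `lat`, `depth`,
#'   `role`, `increment`, `release_day`.
#' @export
design_release_table <- function(design) {
  sw <- design$sweep
  pts <- design$points
  pts$point_id <- pts$id
  all_pts <- pts
  if (sw$parameter == "HS") {
    for (off in sw$increments) {
      inc <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i)
        offset_along_contour(pts[i, ], off, design$topo)))
      inc$point_id <- pts$point_id
      all_pts <- rbind(all_pts, inc)
    }
  } else if (sw$parameter == "VS") {
    for (off in sw$increments) {
      inc <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i)
        offset_depth(pts[i, ], off)))
      inc$point_id <- pts$point_id
      # VS increments keep the baseline's depth band label for pairing
      inc$depth_band <- pts$depth
      all_pts <- rbind(all_pts, cbind(inc[names(pts)]))
    }
  }
  sch <- design$schedule
  n <- nrow(all_pts)
  out <- all_pts[rep(seq_len(n), times = nrow(sch)), ]
  out$release_day <- rep(sch$release_day, each = n)
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Enumerate the particle counts of a design
#'
#' Exact combinatorial counts without running the tracker: baseline
#' tracks, increment tracks and the total particle count.
#'
#' @param design An `experiment_design`.
#' @return List with `baseline_tracks`, `increment_tracks`, `total`,
#'   and the per-component decomposition.
#' @examples
#' # 16 points x 3 depths x 12 monthly releases, 4 HS increments:
#' # 576 baseline tracks, 2880 particles in total.
#' @export
enumerate_design <- function(design) {
  sw <- design$sweep
  n_rel <- nrow(design$schedule)
  base <- design$n_points * length(design$depths) * n_rel
  n_inc <- length(sw$increments)
  if (sw$parameter %in% c("HS", "VS", "TS")) {
    inc <- base * n_inc
  } else if (sw$parameter == "RF") {
    per_year <- attr(design$schedule, "per_year")
    yl <- if (n_rel %% per_year == 0) n_rel / per_year else 1
    inc <- sum(vapply(sw$increments, function(k)
      design$n_points * length(design$depths) * k * yl, numeric(1)))
  } else {  # TR: increment k-year subsets of the baseline years
    n_years <- max(design$schedule$year_index)
    per_year <- n_rel / n_years
    inc <- sum(vapply(sw$increments, function(k)
      design$n_points * length(design$depths) * per_year * k *
        choose(n_years, k), numeric(1)))
  }
  list(parameter = sw$parameter,
       points_per_depth = design$n_points,
       depths = length(design$depths),
       releases = n_rel,
       baseline_tracks = base,
       increment_tracks = inc,
       total = base + inc)
}
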