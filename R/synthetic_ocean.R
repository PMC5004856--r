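# Synthetic depth-stratified ocean: mesoscale stream-function eddies over
# idealized guyot topography, with Ornstein-Uhlenbeck amplitude
# modulation and random-walking eddy centres so that fields decorrelate
# over a configurable timescale.

#' Eddy field parameters
#'
#' Controls the synthetic velocity generator. Each z-level gets a set of
#' Gaussian stream-function vortices of peak amplitude `amplitude[k]`
#' (m^2/s) and horizontal scale `length_scale_km`; eddy centres drift as
#' a random walk and amplitudes follow an Ornstein-Uhlenbeck process
#' with decorrelation timescale `amp_timescale_days` (default 2 days,
#' the scale on which daily averaged mid-latitude currents typically
#' vary). A constant background flow per level can be added.
#'
#' @param amplitude Numeric vector, one stream-function peak (m^2/s) per
#'   z-level; see [eddy_amplitude_for_speed()] to derive amplitudes from
#'   target peak current speeds.
#' @param length_scale_km Eddy e-folding scale L (km), scalar or one
#'   value per z-level; the azimuthal speed of one vortex peaks at
#'   radius L. Smaller L gives patchier velocity fields with stronger
#'   strain at the same speed.
#' @param n_eddies Number of vortices per level-set.
#' @param drift_km_day Standard deviation of the daily random-walk step
#'   of each eddy centre (km).
#' @param amp_timescale_days Amplitude decorrelation timescale (days).
#' @param amp_sd Relative standard deviation of the amplitude modulation.
#' @param background_u,background_v Background flow per level (m/s,
#'   recycled across levels).
#' @param vertical_shift_km Standard deviation of the fixed per-level
#'   offset of each eddy centre, giving partial (not perfect) vertical
#'   coherence between neighbouring levels.
#' @param boundary_taper_m Water-column clearance (m) over which the
#'   stream function is blended towards a boundary-following state
#'   approaching the seamount or land, so the flow largely steers
#'   around topography instead of through it (0 disables the taper).
#' @param boundary_align_floor Fraction of the raw flow retained at the
#'   interface itself (0 = perfectly boundary-aligned, which would trap
#'   released particles on an invariant streamline; the default 0.3
#'   lets near-bottom particles ground or escape).
#' @param seed Integer seed; identical parameters and seed give
#'   bit-identical fields.
#' @return An object of class `eddy_field_params`.
#' @export
eddy_field_params <- function(amplitude,
                              length_scale_km = 40,
                              n_eddies = 90,
                              drift_km_day = 5,
                              amp_timescale_days = 2,
                              amp_sd = 0.6,
                              background_u = 0.008,
                              background_v = 0.004,
                              vertical_shift_km = 8,
                              boundary_taper_m = 1200,
                              boundary_align_floor = 0.1,
                              seed = 1L) {
  stopifnot(all(length_scale_km > 0), n_eddies >= 0, amp_timescale_days > 0,
            amp_sd >= 0, drift_km_day >= 0, vertical_shift_km >= 0,
            boundary_taper_m >= 0,
            boundary_align_floor >= 0, boundary_align_floor <= 1)
  structure(list(amplitude = as.numeric(amplitude),
                 length_scale_km = as.numeric(length_scale_km),
                 n_eddies = as.integer(n_eddies),
                 drift_km_day = drift_km_day,
                 amp_timescale_days = amp_timescale_days,
                 amp_sd = amp_sd,
                 background_u = background_u,
                 background_v = background_v,
                 vertical_shift_km = vertical_shift_km,
                 boundary_taper_m = boundary_taper_m,
                 boundary_align_floor = boundary_align_floor,
                 seed = as.integer(seed)),
            class = "eddy_field_params")
}

#' Stream-function amplitude for a target peak speed
#'
#' For a Gaussian vortex psi = A exp(-r^2 / (2 L^2)) the azimuthal speed
#' peaks at radius L with magnitude A / (L e^{1/2}). Inverts that
#' relation.
#'
#' @param speed Target peak azimuthal speed (m/s).
#' @param length_scale_km Eddy scale L (km).
#' @return Amplitude A in m^2/s.
#' @export
eddy_amplitude_for_speed <- function(speed, length_scale_km = 25) {
  speed * length_scale_km * 1000 * exp(0.5)
}

#' Default depth profile of eddy intensity
#'
#' Peak current speed (m/s) as a function of depth, interpolated through
#' a profile with the greatest mesoscale variability at mid-depth
#' (~1000 m) and the least at 1500 m and below. Used to build the default
#' per-level amplitudes of the synthetic ocean.
#'
#' @param z_levels Depths (m).
#' @return Peak speeds (m/s), one per level.
#' @export
eddy_speed_profile <- function(z_levels) {
  knots_z <- c(0, 150, 700, 1000, 1250, 1500, 2500, 5500)
  knots_v <- c(0.055, 0.055, 0.05, 0.125, 0.045, 0.008, 0.007, 0.006)
  stats::approx(knots_z, knots_v, xout = z_levels, rule = 2)$y
}

#' Default depth profile of eddy length scale
#'
#' Horizontal eddy scale L (km) by depth: mid-depth (~1000 m) fields are
#' patchier (smaller L, hence stronger strain at comparable speed) than
#' shallower levels, and deep levels are smooth and broad.
#'
#' @param z_levels Depths (m).
#' @return Length scales (km), one per level.
#' @export
eddy_length_profile <- function(z_levels) {
  knots_z <- c(0, 150, 700, 1000, 1250, 1500, 2500, 5500)
  knots_l <- c(45, 45, 40, 26, 45, 75, 80, 80)
  stats::approx(knots_z, knots_l, xout = z_levels, rule = 2)$y
}

# Run `expr` with a private RNG stream; the caller's .Random.seed is
# untouched.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic velocity field series
#'
#' Builds horizontal velocity snapshots per z-level from a gridded
#' stream function: psi is the sum of Gaussian vortices (plus a linear
#' term for the background flow), and u = -dpsi/dy, v = +dpsi/dx are
#' taken as central differences of the gridded psi using a fixed local
#' Cartesian metric at the domain mid-latitude. The discrete horizontal
#' divergence of the eddy component therefore vanishes identically, so
#' the flow adds no artificial particle sources or sinks. Velocities are
#' zeroed and masked invalid where the seafloor is shallower than the
#' level.
#'
#' @param grid A [grid_spec()].
#' @param topo A [guyot_topography()] on the same grid.
#' @param params [eddy_field_params()]; `params$amplitude` must have one
#'   entry per `grid$z_levels`.
#' @return An object of class `velocity_field_series`: arrays `u`, `v`
#'   of dim (lon, lat, level, snapshot) in m/s, a node validity array,
#'   and provenance (`params`, seed).
#' @export
generate_velocity_series <- function(grid, topo, params) {
  stopifnot(inherits(grid, "grid_spec"), inherits(topo, "topography"),
            inherits(params, "eddy_field_params"))
  nlev <- length(grid$z_levels)
  amp <- rep_len(params$amplitude, nlev)
  bu <- rep_len(params$background_u, nlev)
  bv <- rep_len(params$background_v, nlev)
  nx <- grid$nlon; ny <- grid$nlat; nt <- grid$n_snapshots
  lat_mid <- (grid$lat_min + grid$lat_max) / 2
  dx <- grid$spacing * m_per_deg_lon(lat_mid)   # m, fixed metric
  dy <- grid$spacing * m_per_deg_lat()
  xm <- (seq_len(nx) - 1) * dx                  # local Cartesian coords
  ym <- (seq_len(ny) - 1) * dy
  Lm <- rep_len(params$length_scale_km, nlev) * 1000

  u <- array(0, c(nx, ny, nlev, nt))
  v <- array(0, c(nx, ny, nlev, nt))
  ne <- params$n_eddies

  .with_seed(params$seed, {
    if (ne > 0) {
      ex0 <- stats::runif(ne, min(xm), max(xm))
      ey0 <- stats::runif(ne, min(ym), max(ym))
      esign <- rep_len(c(1, -1), ne)
      # fixed per-level centre offsets: partial vertical coherence
      ozx <- matrix(stats::rnorm(ne * nlev, 0,
                                 params$vertical_shift_km * 1000), ne, nlev)
      ozy <- matrix(stats::rnorm(ne * nlev, 0,
                                 params$vertical_shift_km * 1000), ne, nlev)
      # time evolution: centre random walk + OU amplitude modulation
      dt <- grid$snapshot_interval
      ex <- matrix(0, ne, nt); ey <- matrix(0, ne, nt)
      am <- matrix(1, ne, nt)
      ex[, 1] <- ex0; ey[, 1] <- ey0
      th <- dt / params$amp_timescale_days
      if (nt > 1) {
        step <- params$drift_km_day * 1000 * sqrt(dt)
        for (k in seq_len(nt - 1)) {
          ex[, k + 1] <- ex[, k] + stats::rnorm(ne, 0, step)
          ey[, k + 1] <- ey[, k] + stats::rnorm(ne, 0, step)
          am[, k + 1] <- am[, k] - th * (am[, k] - 1) +
            params$amp_sd * sqrt(2 * th) * stats::rnorm(ne)
        }
      }
    }
    # per-level clearance taper: psi -> f*psi + (1-f)*psi_boundary, with
    # f rising from 0 at the seamount interface to 1 at
    # `boundary_taper_m` of clearance and psi_boundary the mean stream
    # function over the interface band. The interface becomes a closed
    # streamline, so the flow steers around topography (with the
    # expected flank speed-up) instead of through it.
    tapers <- lapply(seq_len(nlev), function(l) {
      if (params$boundary_taper_m <= 0) return(NULL)
      f <- (topo$depth - grid$z_levels[l]) / params$boundary_taper_m
      f <- pmin(pmax(f, 0), 1)
      if (all(f == 1)) return(NULL)
      # partial alignment: the interface keeps a fraction of the raw
      # flow, so it is steered along topography but is not an exact
      # invariant streamline (particles can leave or ground there)
      fb <- params$boundary_align_floor
      f2 <- fb + (1 - fb) * f
      list(f = f2, band = which(f > 0 & f < 1),
           inside = which(topo$depth < grid$z_levels[l]))
    })
    for (k in seq_len(nt)) {
      for (l in seq_len(nlev)) {
        # psi grid: background flow as linear stream function
        psi <- outer(xm * bv[l], ym * bu[l], function(a, b) a - b)
        if (ne > 0) {
          for (e in seq_len(ne)) {
            r2 <- outer((xm - ex[e, k] - ozx[e, l])^2,
                        (ym - ey[e, k] - ozy[e, l])^2, `+`)
            psi <- psi + esign[e] * amp[l] * am[e, k] *
              exp(-r2 / (2 * Lm[l]^2))
          }
        }
        tp <- tapers[[l]]
        if (!is.null(tp)) {
          psi_b <- if (length(tp$band)) mean(psi[tp$band]) else 0
          psi <- tp$f * psi + (1 - tp$f) * psi_b
        }
        # central differences (one-sided at the edges)
        iu <- -(psi[, c(2:ny, ny)] - psi[, c(1, 1:(ny - 1))])
        iu <- iu / ((col(iu) < ny & col(iu) > 1) + 1) / dy
        iv <- (psi[c(2:nx, nx), ] - psi[c(1, 1:(nx - 1)), ])
        iv <- iv / ((row(iv) < nx & row(iv) > 1) + 1) / dx
        u[, , l, k] <- iu
        v[, , l, k] <- iv
      }
    }
  })

  valid <- .validity_mask(topo, grid$z_levels)
  for (l in seq_len(nlev)) {
    bad <- !valid[, , l]
    if (any(bad)) {
      for (k in seq_len(nt)) {
        uu <- u[, , l, k]; uu[bad] <- 0; u[, , l, k] <- uu
        vv <- v[, , l, k]; vv[bad] <- 0; v[, , l, k] <- vv
      }
    }
  }

  structure(list(grid = grid, topo = topo, params = params,
                 u = u, v = v, valid = valid, seed = params$seed),
            class = "velocity_field_series")
}

#' @export
print.velocity_field_series <- function(x, ...) {
  cat(sprintf(
    "<velocity_field_series> %d x %d x %d levels x %d snapshots (seed %s)\n",
    x$grid$nlon, x$grid$nlat, length(x$grid$z_levels),
    x$grid$n_snapshots, format(x$seed)))
  invisible(x)
}

#' Synthetic velocity series with default study-like configuration
#'
#' One-call constructor of a guyot-centred synthetic ocean: builds the
#' grid, topography and an eddy field whose intensity follows
#' [eddy_speed_profile()] (greatest variability near 1000 m, least at
#' 1500 m).
#'
#' @param z_levels Depths (m) of the levels to generate.
#' @param n_snapshots Number of daily snapshots.
#' @param seed Integer seed.
#' @param half_width_deg Half-width of the square domain (degrees).
#' @param centre_lon,centre_lat Seamount/domain centre.
#' @param ... Further arguments to [eddy_field_params()] (overriding its
#'   defaults; `amplitude` is derived from the speed profile).
#' @return A `velocity_field_series`.
#' @export
synthetic_series <- function(z_levels = c(700, 1000, 1500),
                             n_snapshots = 40,
                             seed = 1L,
                             half_width_deg = 3,
                             centre_lon = -11.0, centre_lat = 57.5,
                             ...) {
  grid <- grid_spec(centre_lon - half_width_deg, centre_lon + half_width_deg,
                    centre_lat - half_width_deg, centre_lat + half_width_deg,
                    z_levels = z_levels, n_snapshots = n_snapshots)
  topo <- guyot_topography(grid, centre_lon, centre_lat)
  dots <- list(...)
  if (is.null(dots$length_scale_km))
    dots$length_scale_km <- eddy_length_profile(z_levels)
  if (is.null(dots$amplitude))
    dots$amplitude <- eddy_amplitude_for_speed(eddy_speed_profile(z_levels),
                                               dots$length_scale_km)
  dots$seed <- seed
  params <- do.call(eddy_field_params, dots)
  generate_velocity_series(grid, topo, params)
}
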