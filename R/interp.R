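# Spatial/temporal interpolation of gridded velocity fields.
#
# The sampling contract mirrors the offline simulator being emulated:
# bicubic interpolation in the horizontal (falling back to bilinear when
# the 4x4 stencil touches an invalid node or the grid edge), linear
# interpolation in depth between bracketing z-levels, and linear
# interpolation in time between daily snapshots.

# Catmull-Rom cubic convolution weights for fractional offset t in [0,1),
# acting on samples at offsets -1, 0, 1, 2. Reproduces values at the
# knots and linear functions exactly.
.catmull_w <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind((-t3 + 2 * t2 - t) / 2,
        (3 * t3 - 5 * t2 + 2) / 2,
        (-3 * t3 + 4 * t2 + t) / 2,
        (t3 - t2) / 2)
}

# Bilinear interpolation on matrix M at fractional 1-based indices.
.bilinear_slice <- function(M, gx, gy) {
  nx <- nrow(M); ny <- ncol(M)
  ix <- pmin(pmax(floor(gx), 1L), nx - 1L)
  iy <- pmin(pmax(floor(gy), 1L), ny - 1L)
  tx <- gx - ix; ty <- gy - iy
  i00 <- ix + (iy - 1L) * nx
  v00 <- M[i00]; v10 <- M[i00 + 1L]
  v01 <- M[i00 + nx]; v11 <- M[i00 + nx + 1L]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

# Bicubic (Catmull-Rom) interpolation on M with validity matrix V.
# Points whose 4x4 stencil leaves the grid or touches an invalid node
# are evaluated bilinearly instead ("linear in the vicinity of land").
.interp_slice <- function(M, V, gx, gy, mode = c("cubic", "linear")) {
  mode <- match.arg(mode)
  if (mode == "linear") return(.bilinear_slice(M, gx, gy))
  nx <- nrow(M); ny <- ncol(M)
  ix <- pmin(pmax(floor(gx), 1L), nx - 1L)
  iy <- pmin(pmax(floor(gy), 1L), ny - 1L)
  tx <- gx - ix; ty <- gy - iy
  cubic_ok <- ix >= 2L & ix <= nx - 2L & iy >= 2L & iy <= ny - 2L
  out <- numeric(length(gx))
  if (any(cubic_ok)) {
    cx <- ix[cubic_ok]; cy <- iy[cubic_ok]
    wx <- .catmull_w(tx[cubic_ok]); wy <- .catmull_w(ty[cubic_ok])
    rowvals <- matrix(0, sum(cubic_ok), 4L)
    valid_all <- rep(TRUE, sum(cubic_ok))
    base <- cx - 1L
    for (b in 0:3) {
      col0 <- (cy - 2L + b) * nx
      acc <- numeric(sum(cubic_ok))
      for (a in 0:3) {
        idx <- base + a + col0
        acc <- acc + wx[, a + 1L] * M[idx]
        if (!is.null(V)) valid_all <- valid_all & V[idx]
      }
      rowvals[, b + 1L] <- acc
    }
    cub <- rowSums(rowvals * wy)
    res <- numeric(sum(cubic_ok))
    res[valid_all] <- cub[valid_all]
    if (any(!valid_all)) {
      res[!valid_all] <- .bilinear_slice(M, gx[cubic_ok][!valid_all],
                                         gy[cubic_ok][!valid_all])
    }
    out[cubic_ok] <- res
  }
  if (any(!cubic_ok))
    out[!cubic_ok] <- .bilinear_slice(M, gx[!cubic_ok], gy[!cubic_ok])
  out
}

# Core vectorised velocity sampler. `time` is days since the series
# origin (scalar or vector). Returns list(u, v, oob) where oob marks
# queries outside the horizontal bounds or time span (u/v are NA there).
.sample_uv <- function(series, lon, lat, depth, time,
                       mode = c("cubic", "linear")) {
  mode <- match.arg(mode)
  grid <- series$grid
  n <- length(lon)
  time <- rep_len(time, n)
  depth <- rep_len(depth, n)
  u <- rep(NA_real_, n); v <- rep(NA_real_, n)
  tmax <- grid$snapshot_days[grid$n_snapshots]
  oob <- !(.in_bounds(grid, lon, lat) & time >= 0 & time <= tmax + 1e-9)
  ok <- which(!oob)
  if (length(ok) == 0L) return(list(u = u, v = v, oob = oob))

  gi <- .grid_index(grid, lon[ok], lat[ok])
  # time bracket (linear between snapshots)
  gt <- pmin(pmax(time[ok] / grid$snapshot_interval, 0), grid$n_snapshots - 1)
  k0 <- pmin(floor(gt) + 1L, grid$n_snapshots - 1L)
  k0 <- pmax(k0, 1L)
  if (grid$n_snapshots == 1L) k0 <- rep(1L, length(gt))
  wt <- gt - (k0 - 1L)
  # depth bracket (linear between z-levels; clamped outside the range)
  zl <- grid$z_levels
  l0 <- findInterval(depth[ok], zl, rightmost.closed = TRUE)
  l0 <- pmin(pmax(l0, 1L), max(length(zl) - 1L, 1L))
  if (length(zl) == 1L) {
    wz <- rep(0, length(l0))
  } else {
    wz <- (depth[ok] - zl[l0]) / (zl[l0 + 1L] - zl[l0])
    wz <- pmin(pmax(wz, 0), 1)
  }

  # With the clamping above, level l0+1 and snapshot k0+1 always exist
  # whenever their weights can be nonzero (wz = 0 when there is a single
  # level, wt = 0 when there is a single snapshot).
  us <- numeric(length(ok)); vs <- numeric(length(ok))
  groups <- split(seq_along(ok), list(l0, k0), drop = TRUE)
  for (g in groups) {
    lev <- l0[g[1L]]; kk <- k0[g[1L]]
    gx <- gi$gx[g]; gy <- gi$gy[g]
    wzg <- wz[g]; wtg <- wt[g]
    lev1 <- min(lev + 1L, length(zl))
    kk1 <- min(kk + 1L, grid$n_snapshots)
    acc_u <- 0; acc_v <- 0
    for (dz in 0:1) {
      zw <- if (dz == 0) 1 - wzg else wzg
      if (dz == 1 && lev1 == lev) next
      L <- if (dz == 0) lev else lev1
      Vm <- series$valid[, , L]
      for (dt in 0:1) {
        tw <- if (dt == 0) 1 - wtg else wtg
        if (dt == 1 && kk1 == kk) next
        K <- if (dt == 0) kk else kk1
        w <- zw * tw
        if (all(w == 0)) next
        acc_u <- acc_u + w * .interp_slice(series$u[, , L, K], Vm, gx, gy, mode)
        acc_v <- acc_v + w * .interp_slice(series$v[, , L, K], Vm, gx, gy, mode)
      }
    }
    us[g] <- acc_u; vs[g] <- acc_v
  }
  u[ok] <- us; v[ok] <- vs
  list(u = u, v = v, oob = oob)
}

#' Sample velocity from a field series
#'
#' Interpolates the horizontal velocity at arbitrary positions, depths
#' and times: bicubic in the horizontal (bilinear where the 16-node
#' stencil touches the grid edge or a masked node), linear in depth
#' between bracketing z-levels, linear in time between snapshots.
#'
#' @param series A velocity field series (see
#'   [generate_velocity_series()] or [read_fields()]).
#' @param lon,lat Positions in degrees (vectorised).
#' @param depth Depth in metres, positive down.
#' @param time Days since the series time origin.
#' @param mode `"cubic"` (default) or `"linear"` horizontal interpolation.
#' @return A data frame with columns `u`, `v` (m/s).
#' @export
sample_velocity <- function(series, lon, lat, depth, time,
                            mode = c("cubic", "linear")) {
  res <- .sample_uv(series, lon, lat, depth, time, match.arg(mode))
  if (any(res$oob))
    stop("query outside the grid bounds or time span")
  data.frame(u = res$u, v = res$v)
}
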