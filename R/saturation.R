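# Model-saturation engine: track-density rasters (distinct tracks per
# cell, polylines traversed by exact segment-grid intersection), the
# fraction of unexplained variance FUV = 1 - r^2 between density
# rasters, 95th-percentile envelopes over replicates, and the
# down-crossing of the saturation threshold.

#' Raster specification for track densities
#'
#' @param lon_min,lat_min Raster origin (lower-left cell edge, degrees).
#' @param cell Cell size in degrees; the default 0.04 is half a typical
#'   0.08-degree field resolution.
#' @param nx,ny Cell counts (may grow if tracks leave the extent).
#' @return An object of class `raster_spec`.
#' @export
raster_spec <- function(lon_min, lat_min, nx, ny, cell = 0.04) {
  stopifnot(cell > 0, nx >= 1, ny >= 1)
  structure(list(lon_min = lon_min, lat_min = lat_min,
                 nx = as.integer(nx), ny = as.integer(ny), cell = cell),
            class = "raster_spec")
}

#' Raster spec covering a grid
#'
#' @param grid A [grid_spec()].
#' @param cell Cell size in degrees (default half the grid spacing).
#' @export
raster_spec_for_grid <- function(grid, cell = grid$spacing / 2) {
  raster_spec(grid$lon_min, grid$lat_min,
              nx = ceiling((grid$lon_max - grid$lon_min) / cell),
              ny = ceiling((grid$lat_max - grid$lat_min) / cell),
              cell = cell)
}

# Cells entered by segments. Exact traversal: for each segment all
# crossings with the vertical and horizontal cell edges are found, the
# segment is cut there, and each piece's midpoint identifies a cell.
# Vectorised across segments. Returns unique (track, cell index) pairs.
.traverse_cells <- function(spec, track_id, x0, y0, x1, y1) {
  gx0 <- (x0 - spec$lon_min) / spec$cell
  gy0 <- (y0 - spec$lat_min) / spec$cell
  gx1 <- (x1 - spec$lon_min) / spec$cell
  gy1 <- (y1 - spec$lat_min) / spec$cell
  ns <- length(gx0)
  cx0 <- floor(gx0); cx1 <- floor(gx1)
  cy0 <- floor(gy0); cy1 <- floor(gy1)
  nxc <- abs(cx1 - cx0); nyc <- abs(cy1 - cy0)
  # crossing parameters t in (0,1) with vertical grid lines
  tx <- if (sum(nxc) > 0) {
    seg <- rep.int(seq_len(ns), nxc)
    kth <- sequence(nxc)
    lo <- pmin(cx0, cx1)[seg]
    line <- lo + kth                       # crossed vertical line index
    (line - gx0[seg]) / (gx1 - gx0)[seg]
  } else numeric(0)
  segx <- rep.int(seq_len(ns), nxc)
  ty <- if (sum(nyc) > 0) {
    seg <- rep.int(seq_len(ns), nyc)
    kth <- sequence(nyc)
    lo <- pmin(cy0, cy1)[seg]
    line <- lo + kth
    (line - gy0[seg]) / (gy1 - gy0)[seg]
  } else numeric(0)
  segy <- rep.int(seq_len(ns), nyc)
  seg_all <- c(segx, segy, seq_len(ns), seq_len(ns))
  t_all <- c(tx, ty, rep(0, ns), rep(1, ns))
  o <- order(seg_all, t_all)
  seg_all <- seg_all[o]; t_all <- t_all[o]
  # midpoints of consecutive cut points within each segment
  same <- c(seg_all[-1] == seg_all[-length(seg_all)], FALSE)
  tm <- (t_all + c(t_all[-1], 0)) / 2
  seg_m <- seg_all[same]; tm <- tm[same]
  mx <- gx0[seg_m] + tm * (gx1 - gx0)[seg_m]
  my <- gy0[seg_m] + tm * (gy1 - gy0)[seg_m]
  ix <- floor(mx); iy <- floor(my)
  data.frame(track = track_id[seg_m], ix = ix, iy = iy)
}

#' Rasterize tracks into a track-density grid
#'
#' Each track becomes a polyline through its daily positions; every
#' raster cell the polyline enters gets that track's indicator, and the
#' cell count is the number of distinct tracks entering it -- no track
#' is counted twice in a cell, however often it loops back. Cell
#' traversal is by exact segment-grid intersection, so cells skipped
#' over by a long daily displacement are still credited. Positions
#' outside the extent expand the raster (the final extent is recorded
#' in the result).
#'
#' @param tracks A `track_set` (see [run_release_set()]), a
#'   `disp_track`, or a list of objects with `lon`/`lat` vectors.
#' @param spec A [raster_spec()].
#' @return An object of class `density_raster`: integer `counts` matrix
#'   (nx x ny) plus the (possibly expanded) spec.
#' @export
rasterize_tracks <- function(tracks, spec) {
  if (inherits(tracks, "disp_track")) tracks <- list(tracks)
  if (inherits(tracks, "track_set")) {
    lonM <- tracks$lon; latM <- tracks$lat
  } else {
    lonM <- do.call(rbind, lapply(tracks, `[[`, "lon"))
    latM <- do.call(rbind, lapply(tracks, `[[`, "lat"))
  }
  n <- nrow(lonM)
  if (is.null(n) || n == 0L) {
    counts <- matrix(0L, spec$nx, spec$ny)
    return(structure(list(counts = counts, spec = spec),
                     class = "density_raster"))
  }
  nrec <- ncol(lonM)
  # expand the spec to cover every position
  rng_x <- range(lonM, na.rm = TRUE); rng_y <- range(latM, na.rm = TRUE)
  lon_min <- min(spec$lon_min, floor((rng_x[1] - spec$lon_min) /
                                       spec$cell) * spec$cell + spec$lon_min)
  lat_min <- min(spec$lat_min, floor((rng_y[1] - spec$lat_min) /
                                       spec$cell) * spec$cell + spec$lat_min)
  nx <- max(spec$nx + round((spec$lon_min - lon_min) / spec$cell),
            ceiling((rng_x[2] - lon_min) / spec$cell + 1e-9))
  ny <- max(spec$ny + round((spec$lat_min - lat_min) / spec$cell),
            ceiling((rng_y[2] - lat_min) / spec$cell + 1e-9))
  spec2 <- raster_spec(lon_min, lat_min, nx, ny, spec$cell)

  sid <- rep(seq_len(n), nrec - 1L)
  x0 <- as.vector(lonM[, -nrec]); x1 <- as.vector(lonM[, -1])
  y0 <- as.vector(latM[, -nrec]); y1 <- as.vector(latM[, -1])
  keep <- !(is.na(x0) | is.na(x1) | is.na(y0) | is.na(y1))
  cells <- .traverse_cells(spec2, sid[keep], x0[keep], y0[keep],
                           x1[keep], y1[keep])
  cells$ix <- pmin(pmax(cells$ix, 0L), spec2$nx - 1L)
  cells$iy <- pmin(pmax(cells$iy, 0L), spec2$ny - 1L)
  key <- cells$ix + cells$iy * spec2$nx +
    (cells$track - 1) * (spec2$nx * spec2$ny)
  ucell <- unique(key) %% (spec2$nx * spec2$ny)
  counts <- matrix(0L, spec2$nx, spec2$ny)
  tab <- table(ucell)
  idx <- as.integer(names(tab)) + 1L
  counts[idx] <- as.integer(tab)
  structure(list(counts = counts, spec = spec2),
            class = "density_raster")
}

#' @export
print.density_raster <- function(x, ...) {
  cat(sprintf("<density_raster> %d x %d cells of %g deg, max count %d\n",
              x$spec$nx, x$spec$ny, x$spec$cell, max(x$counts)))
  invisible(x)
}

# Align two density rasters onto the union extent, padding with zeros.
.align_rasters <- function(a, b) {
  if (a$spec$cell != b$spec$cell)
    stop("rasters have different cell sizes")
  cell <- a$spec$cell
  lon_min <- min(a$spec$lon_min, b$spec$lon_min)
  lat_min <- min(a$spec$lat_min, b$spec$lat_min)
  nx <- max(round((a$spec$lon_min - lon_min) / cell) + a$spec$nx,
            round((b$spec$lon_min - lon_min) / cell) + b$spec$nx)
  ny <- max(round((a$spec$lat_min - lat_min) / cell) + a$spec$ny,
            round((b$spec$lat_min - lat_min) / cell) + b$spec$ny)
  pad <- function(r) {
    M <- matrix(0L, nx, ny)
    ox <- round((r$spec$lon_min - lon_min) / cell)
    oy <- round((r$spec$lat_min - lat_min) / cell)
    M[ox + seq_len(r$spec$nx), oy + seq_len(r$spec$ny)] <- r$counts
    M
  }
  list(a = pad(a), b = pad(b))
}

#' Fraction of unexplained variance between two density rasters
#'
#' Pearson correlation r between the two rasters cell by cell, and
#' FUV = 1 - r^2. Rasters are aligned onto their union extent (zero
#' padded); the correlated cell set is the cells nonzero in at least
#' one raster, so the score does not depend on how much empty ocean
#' surrounds the tracks.
#'
#' @param a,b `density_raster` objects on the same cell size.
#' @return List of class `fuv_score` with `r`, `fuv`, `n_cells`.
#' @export
fuv <- function(a, b) {
  al <- .align_rasters(a, b)
  use <- al$a != 0 | al$b != 0
  x <- as.numeric(al$a[use]); y <- as.numeric(al$b[use])
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: a raster has zero variance over the ",
         "compared cells")
  r <- stats::cor(x, y)
  structure(list(r = r, fuv = 1 - r^2, n_cells = length(x)),
            class = "fuv_score")
}

#' @export
print.fuv_score <- function(x, ...) {
  cat(sprintf("<fuv_score> r = %.4f, FUV = %.4f over %d cells\n",
              x$r, x$fuv, x$n_cells))
  invisible(x)
}

#' 95th-percentile envelope of replicate FUV values
#'
#' Per increment, the 95th percentile of the replicate FUV scores
#' (quantile by linear interpolation between order statistics), so that
#' 95% of replicates fall below the envelope. A shape-preserving
#' piecewise cubic Hermite interpolant through these knots is the curve
#' whose threshold crossing defines the optimal value.
#'
#' @param increments Increment values (one per replicate set).
#' @param fuv_sets List of numeric vectors of replicate FUVs, parallel
#'   to `increments`.
#' @param probs Envelope percentile (default 0.95).
#' @return Data frame of class `fuv_envelope` with `increment` and
#'   `q95`.
#' @export
fuv_envelope <- function(increments, fuv_sets, probs = 0.95) {
  if (length(increments) != length(fuv_sets))
    stop("one replicate set per increment required")
  if (any(vapply(fuv_sets, length, integer(1)) < 1))
    stop("empty replicate set")
  q <- vapply(fuv_sets, function(v)
    stats::quantile(v, probs, type = 7, names = FALSE), numeric(1))
  structure(data.frame(increment = increments, q95 = q),
            class = c("fuv_envelope", "data.frame"))
}

#' Optimal value from a saturation envelope
#'
#' FUV decreases towards the high-resolution baseline; this returns the
#' smallest increment resolution at which the envelope first drops to
#' the threshold (shared down-crossing routine; linear-continuation
#' estimate flagged as extrapolated when the envelope never reaches it).
#'
#' @param envelope A [fuv_envelope()] (or data frame with `increment`,
#'   `q95`).
#' @param threshold Saturation threshold on FUV (default 0.05).
#' @return List with `optimal` and `extrapolated` flag.
#' @export
optimal_from_envelope <- function(envelope, threshold = 0.05) {
  fit_threshold_crossing(envelope$increment, envelope$q95, threshold,
                         direction = "down")
}

#' Back-compute a correlation from an FUV score
#'
#' Inverts FUV = 1 - r^2: r = sqrt(1 - FUV). Useful to report what a
#' sub-optimal setting's saturation score means as a map correlation.
#'
#' @param fuv FUV value(s) in `[0, 1]`.
#' @return Correlation r.
#' @examples
#' fuv_to_correlation(0.05)  # 0.9747
#' @export
fuv_to_correlation <- function(fuv) {
  if (any(fuv < 0 | fuv > 1)) stop("FUV must lie in [0, 1]")
  sqrt(1 - fuv)
}

#' Export a density raster as ESRI ASCII grid
#'
#' @param x A `density_raster`.
#' @param path Output path.
#' @export
write_raster_ascii <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", x$spec$nx),
               sprintf("nrows %d", x$spec$ny),
               sprintf("xllcorner %.10g", x$spec$lon_min),
               sprintf("yllcorner %.10g", x$spec$lat_min),
               sprintf("cellsize %.10g", x$spec$cell),
               "NODATA_value -9999"), con)
  for (j in rev(seq_len(x$spec$ny)))
    writeLines(paste(x$counts[, j], collapse = " "), con)
  invisible(path)
}
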