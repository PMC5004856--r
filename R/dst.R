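# Spatial-autocorrelation engine: Distance Separation over Time (DST)
# between baseline and increment tracks, pooled medians, and
# threshold-crossing optimal values.

#' Great-circle distance (haversine)
#'
#' Haversine distance on a sphere of radius 6371 km, the separation
#' metric used for all track comparisons.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees (vectorised,
#'   recycled to a common length).
#' @param radius_km Sphere radius in km.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 1, 0)  # one degree of longitude at the equator
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2,
                         radius_km = EARTH_RADIUS_KM) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * radius_km * asin(sqrt(a))
}

#' Distance separation over time between two tracks
#'
#' The per-day great-circle distance between the daily positions of a
#' baseline track and an increment track released at the same time with
#' the same planktonic larval duration. Day 0 (the release positions) is
#' excluded; the series covers days `1..PLD`. Positions frozen by
#' beaching or domain escape are compared as recorded.
#'
#' @param baseline,increment Tracks from [advect_particle()], or any
#'   lists with numeric `lon`, `lat`, `day` elements of equal length.
#' @return An object of class `dst_series`: data frame with `day` and
#'   `dst_km`.
#' @export
dst_series <- function(baseline, increment) {
  if (length(baseline$lon) != length(increment$lon))
    stop("tracks have different lengths (PLD or output interval mismatch)")
  keep <- baseline$day >= 1
  d <- haversine_km(baseline$lon[keep], baseline$lat[keep],
                    increment$lon[keep], increment$lat[keep])
  structure(data.frame(day = baseline$day[keep], dst_km = d),
            class = c("dst_series", "data.frame"))
}

# DST matrix for paired rows of a track_set: rows of `pairs` give
# (baseline row index, increment row index). Returns days x npairs matrix.
.dst_matrix <- function(tracks, pairs) {
  keep <- which(tracks$days >= 1)
  nb <- pairs[, 1L]; ni <- pairs[, 2L]
  d <- haversine_km(t(tracks$lon[nb, keep, drop = FALSE]),
                    t(tracks$lat[nb, keep, drop = FALSE]),
                    t(tracks$lon[ni, keep, drop = FALSE]),
                    t(tracks$lat[ni, keep, drop = FALSE]))
  matrix(d, nrow = length(keep))
}

#' Pool DST series into a per-increment summary
#'
#' Pools every replicate pair (release locations x release times) and
#' every tracking day `1..PLD` into a single distribution and reports
#' its median, quartiles, Tukey fences (1.5 IQR) and sample count --
#' the statistic compared against the autocorrelation threshold.
#'
#' @param series_set A list of [dst_series()] objects (or a single one).
#' @param depth Depth band label (m) carried into the summary.
#' @param increment Increment value carried into the summary.
#' @return A one-row data frame of class `dst_summary`.
#' @export
pool_dst <- function(series_set, depth = NA_real_, increment = NA_real_) {
  if (inherits(series_set, "dst_series")) series_set <- list(series_set)
  if (length(series_set) == 0) stop("empty DST series set")
  vals <- unlist(lapply(series_set, function(s) s$dst_km), use.names = FALSE)
  if (length(vals) == 0) stop("empty DST series set")
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  structure(data.frame(depth = depth, increment = increment,
                       median_km = q[2], q1 = q[1], q3 = q[3],
                       fence_lo = q[1] - 1.5 * iqr,
                       fence_hi = q[3] + 1.5 * iqr,
                       n = length(vals)),
            class = c("dst_summary", "data.frame"))
}

#' Per-day median DST and first independence day
#'
#' The per-day median across replicate pairs, plus the first tracking day
#' on which the median reaches the independence threshold (`NA` if it
#' never does). Shows how parameter sensitivity depends on the tracked
#' planktonic larval duration.
#'
#' @inheritParams pool_dst
#' @param threshold_km Independence threshold (km), default 10.
#' @return List with `by_day` (data frame `day`, `median_km`) and
#'   `first_independent_day`.
#' @export
dst_by_day <- function(series_set, threshold_km = 10) {
  if (inherits(series_set, "dst_series")) series_set <- list(series_set)
  days <- series_set[[1]]$day
  m <- vapply(series_set, function(s) {
    if (!identical(length(s$day), length(days)))
      stop("DST series do not share a PLD")
    s$dst_km
  }, numeric(length(days)))
  med <- apply(matrix(m, nrow = length(days)), 1, stats::median)
  hit <- which(med >= threshold_km)
  list(by_day = data.frame(day = days, median_km = med),
       first_independent_day = if (length(hit)) days[hit[1]] else NA_real_)
}
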