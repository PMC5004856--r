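# Shape-preserving interpolation of sensitivity knots and extraction of
# threshold crossings ("optimal values"). Shared by the DST engine
# (up-crossing of the autocorrelation threshold) and the FUV engine
# (down-crossing of the saturation threshold).

# Evaluate the piecewise cubic Hermite interpolant (MATLAB-style pchip)
# through (x, y) at points xq, with linear continuation beyond the knot
# range using the end Hermite slopes.
.pchip_eval <- function(x, y, xq) {
  n <- length(x)
  if (n == 1L) return(rep(y, length(xq)))
  if (n == 2L) {  # two knots: the Hermite interpolant is the chord
    s <- (y[2] - y[1]) / (x[2] - x[1])
    return(y[1] + s * (xq - x[1]))
  }
  out <- numeric(length(xq))
  inside <- xq >= x[1] & xq <= x[n]
  if (any(inside)) out[inside] <- pracma::pchip(x, y, xq[inside])
  if (any(!inside)) {
    h <- min(diff(x)) * 1e-6
    s1 <- (pracma::pchip(x, y, x[1] + h) - y[1]) / h
    sn <- (y[n] - pracma::pchip(x, y, x[n] - h)) / h
    lo <- !inside & xq < x[1]
    hi <- !inside & xq > x[n]
    out[lo] <- y[1] + s1 * (xq[lo] - x[1])
    out[hi] <- y[n] + sn * (xq[hi] - x[n])
  }
  out
}

#' Threshold crossing of a sensitivity curve
#'
#' Fits a shape-preserving piecewise cubic Hermite interpolant through
#' `(increment, statistic)` knots and returns the smallest increment at
#' which the curve first reaches the threshold: an up-crossing
#' (`direction = "up"`, DST-style curves that grow away from the
#' baseline) finds the first point where the curve rises to the
#' threshold; a down-crossing (`direction = "down"`, FUV-style curves
#' that decay towards the baseline) finds the first point where it drops
#' to the threshold. The crossing is located by bisection to a relative
#' tolerance of 1e-6. If the curve never reaches the threshold inside
#' the knot range, the crossing of the linear continuation with the end
#' Hermite slope is returned and flagged as extrapolated.
#'
#' @param increments Knot x-values (distinct, any order).
#' @param statistics Knot y-values.
#' @param threshold Threshold on the statistic.
#' @param direction `"up"` or `"down"`.
#' @param anchor Optional `c(x, y)` knot prepended to the data; DST
#'   sweeps anchor at (baseline increment, 0) because the baseline's
#'   separation from itself is exactly zero.
#' @return List with `optimal` (the crossing increment, `NA` if the
#'   extrapolation never reaches the threshold) and `extrapolated` flag.
#' @export
fit_threshold_crossing <- function(increments, statistics, threshold,
                                   direction = c("up", "down"),
                                   anchor = NULL) {
  direction <- match.arg(direction)
  x <- as.numeric(increments); y <- as.numeric(statistics)
  if (!is.null(anchor)) { x <- c(anchor[1], x); y <- c(anchor[2], y) }
  if (anyDuplicated(x)) stop("duplicate increment values")
  o <- order(x); x <- x[o]; y <- y[o]
  if (length(x) < 2) stop("need at least two knots")
  sgn <- if (direction == "up") 1 else -1
  f <- function(z) sgn * (.pchip_eval(x, y, z) - threshold)
  # exact hits at knots take precedence (smallest such increment)
  hit <- which(abs(y - threshold) == 0)

  # scan knot intervals for the first sign change to non-negative
  n <- length(x)
  crossing <- NA_real_
  for (i in seq_len(n - 1L)) {
    if (length(hit) && x[hit[1]] <= x[i + 1]) break
    a <- x[i]; b <- x[i + 1]
    fa <- f(a); fb <- f(b)
    if (fa >= 0) { crossing <- a; break }
    # sample inside the interval too: pchip can overshoot mid-interval
    zs <- seq(a, b, length.out = 17L)
    fz <- f(zs)
    jj <- which(fz >= 0)
    if (length(jj)) {
      lo <- zs[jj[1] - 1L]; hi <- zs[jj[1]]
      for (k in 1:80) {
        mid <- (lo + hi) / 2
        if (f(mid) >= 0) hi <- mid else lo <- mid
        if ((hi - lo) <= 1e-6 * max(abs(hi), 1e-12)) break
      }
      crossing <- hi
      break
    }
  }
  if (length(hit) && (is.na(crossing) || x[hit[1]] <= crossing))
    crossing <- x[hit[1]]
  if (!is.na(crossing))
    return(list(optimal = unname(crossing), extrapolated = FALSE))
  if (f(x[n]) >= 0)
    return(list(optimal = unname(x[n]), extrapolated = FALSE))
  # linear continuation with the end slope
  h <- min(diff(x)) * 1e-6
  slope <- (.pchip_eval(x, y, x[n]) - .pchip_eval(x, y, x[n] - h)) / h
  gap <- threshold - .pchip_eval(x, y, x[n])
  est <- if (sgn * slope > 0) x[n] + gap / slope else NA_real_
  list(optimal = unname(est), extrapolated = TRUE)
}

#' Build a sensitivity curve from pooled DST summaries
#'
#' Convenience wrapper tying [pool_dst()] output to
#' [fit_threshold_crossing()] for one depth band: knots are the pooled
#' medians per increment, anchored at (baseline, 0), and the optimal
#' value is the first up-crossing of the DST threshold.
#'
#' @param summaries Data frame with `increment` and `median_km` columns
#'   (rows for one depth band).
#' @param baseline Baseline increment value (x of the anchor knot).
#' @param threshold_km DST independence threshold in km.
#' @param depth Depth band label.
#' @return An object of class `sensitivity_curve`.
#' @export
sensitivity_curve <- function(summaries, baseline = 0, threshold_km = 10,
                              depth = NA_real_) {
  cr <- fit_threshold_crossing(summaries$increment, summaries$median_km,
                               threshold_km, direction = "up",
                               anchor = c(baseline, 0))
  structure(list(depth = depth,
                 knots = data.frame(
                   increment = c(baseline, summaries$increment),
                   statistic = c(0, summaries$median_km)),
                 threshold = threshold_km,
                 optimal = cr$optimal, extrapolated = cr$extrapolated),
            class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat(sprintf("<sensitivity_curve> depth %s m: optimal %g%s (threshold %g)\n",
              format(x$depth), x$optimal,
              if (x$extrapolated) " (approx.)" else "", x$threshold))
  invisible(x)
}

#' @export
plot.sensitivity_curve <- function(x, xlab = "increment",
                                   ylab = "median DST (km)", ...) {
  k <- x$knots
  xs <- seq(min(k$increment), max(k$increment), length.out = 200)
  ys <- .pchip_eval(k$increment, k$statistic, xs)
  graphics::plot(xs, ys, type = "l", xlab = xlab, ylab = ylab, ...)
  graphics::points(k$increment, k$statistic, pch = 19)
  graphics::abline(h = x$threshold, lty = 2)
  if (!is.na(x$optimal) && !x$extrapolated)
    graphics::abline(v = x$optimal, lty = 3)
  invisible(x)
}
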