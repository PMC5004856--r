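# Independent oracles shared across test files.

# Dense evaluation of the shape-preserving interpolant on a fine grid;
# brute-force threshold crossing.
dense_crossing <- function(x, y, threshold, direction = "up",
                           step = 1e-4) {
  xs <- seq(min(x), max(x), by = step)
  ys <- larvalsens:::.pchip_eval(sort(x), y[order(x)], xs)
  hit <- if (direction == "up") which(ys >= threshold)
         else which(ys <= threshold)
  if (length(hit) == 0) NA_real_ else xs[hit[1]]
}

# Dense point sampling of a polyline at 1/50 cell-size steps: the cell
# set an exact traversal must reproduce.
sampled_cells <- function(lons, lats, spec) {
  step <- spec$cell / 50
  cx <- integer(0); cy <- integer(0)
  for (i in seq_len(length(lons) - 1)) {
    len <- max(abs(lons[i + 1] - lons[i]), abs(lats[i + 1] - lats[i]))
    n <- max(2, ceiling(len / step))
    t <- seq(0, 1, length.out = n)
    cx <- c(cx, floor((lons[i] + t * (lons[i + 1] - lons[i]) -
                         spec$lon_min) / spec$cell))
    cy <- c(cy, floor((lats[i] + t * (lats[i + 1] - lats[i]) -
                         spec$lat_min) / spec$cell))
  }
  unique(paste(cx, cy))
}
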