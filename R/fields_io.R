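# Plain-text serialisation of velocity field series. The format is a
# self-describing whitespace grid dump: a header of `key: value` lines
# (grid geometry, z-levels, time axis, seed provenance), then one block
# per (variable, level, snapshot) of nlat rows x nlon columns. Values
# are written with 17 significant digits so round-trips are lossless.

#' Write a velocity field series to a text file
#'
#' @param series A `velocity_field_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_fields()]
#' @export
write_fields <- function(series, path) {
  grid <- series$grid
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("format: larvalsens-fields 1")
  wl("lon_min: %.17g", grid$lon_min)
  wl("lat_min: %.17g", grid$lat_min)
  wl("spacing: %.17g", grid$spacing)
  wl("nlon: %d", grid$nlon)
  wl("nlat: %d", grid$nlat)
  wl("z_levels: %s", paste(sprintf("%.17g", grid$z_levels), collapse = " "))
  wl("time_origin: %s", format(grid$time_origin))
  wl("n_snapshots: %d", grid$n_snapshots)
  wl("snapshot_interval: %.17g", grid$snapshot_interval)
  wl("seed: %s", if (is.null(series$seed)) "NA" else format(series$seed))
  dump_block <- function(tag, M) {
    wl("block: %s", tag)
    writeLines(apply(M, 2, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  for (k in seq_len(grid$n_snapshots))
    for (l in seq_along(grid$z_levels)) {
      dump_block(sprintf("u %d %d", l, k), series$u[, , l, k])
      dump_block(sprintf("v %d %d", l, k), series$v[, , l, k])
    }
  for (l in seq_along(grid$z_levels))
    dump_block(sprintf("valid %d 1", l),
               matrix(as.numeric(series$valid[, , l]),
                      grid$nlon, grid$nlat))
  if (!is.null(series$topo))
    dump_block("topo 1 1", series$topo$depth)
  invisible(path)
}

#' Read a velocity field series from a text file
#'
#' Parses the format written by [write_fields()]. Malformed files raise
#' an error naming the missing or offending attribute.
#'
#' @param path File path.
#' @return A `velocity_field_series`; the validity mask and (when
#'   present in the file) the gridded topography are carried in full.
#' @export
read_fields <- function(path) {
  lines <- readLines(path)
  hdr <- list(); i <- 1L
  while (i <= length(lines) && grepl("^[a-z_]+:", lines[i])) {
    key <- sub(":.*$", "", lines[i])
    val <- sub("^[a-z_]+:\\s*", "", lines[i])
    if (key == "block") break
    hdr[[key]] <- val
    i <- i + 1L
  }
  need <- c("lon_min", "lat_min", "spacing", "nlon", "nlat", "z_levels",
            "time_origin", "n_snapshots", "snapshot_interval")
  for (k in need)
    if (is.null(hdr[[k]]))
      stop("malformed field file: missing attribute '", k, "'")
  num <- function(k) {
    x <- suppressWarnings(as.numeric(hdr[[k]]))
    if (any(is.na(x))) stop("malformed field file: bad value for '", k, "'")
    x
  }
  zl <- suppressWarnings(as.numeric(strsplit(trimws(hdr$z_levels),
                                             "\\s+")[[1]]))
  if (length(zl) == 0 || any(is.na(zl)))
    stop("malformed field file: bad value for 'z_levels'")
  nlon <- as.integer(num("nlon")); nlat <- as.integer(num("nlat"))
  nt <- as.integer(num("n_snapshots")); nlev <- length(zl)
  grid <- grid_spec(num("lon_min"), num("lon_min") + (nlon - 1) * num("spacing"),
                    num("lat_min"), num("lat_min") + (nlat - 1) * num("spacing"),
                    spacing = num("spacing"), z_levels = zl,
                    time_origin = hdr$time_origin,
                    n_snapshots = nt,
                    snapshot_interval = num("snapshot_interval"))
  u <- array(NA_real_, c(nlon, nlat, nlev, nt))
  v <- array(NA_real_, c(nlon, nlat, nlev, nt))
  valid <- array(TRUE, c(nlon, nlat, nlev))
  topo <- NULL
  while (i <= length(lines)) {
    if (!grepl("^block:", lines[i]))
      stop("malformed field file: expected 'block:' at line ", i)
    tag <- strsplit(trimws(sub("^block:\\s*", "", lines[i])), "\\s+")[[1]]
    if (length(tag) != 3)
      stop("malformed field file: bad block tag at line ", i)
    var <- tag[1]; l <- as.integer(tag[2]); k <- as.integer(tag[3])
    if (is.na(l) || is.na(k) || l < 1 || l > nlev || k < 1 || k > nt)
      stop("malformed field file: block indices out of range at line ", i)
    rows <- lines[(i + 1):(i + nlat)]
    M <- t(vapply(rows, function(r) {
      x <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
      if (length(x) != nlon || any(is.na(x)))
        stop("malformed field file: bad data row in block '",
             paste(tag, collapse = " "), "'")
      x
    }, numeric(nlon), USE.NAMES = FALSE))
    M <- t(M)  # back to nlon x nlat
    switch(var,
           u = { u[, , l, k] <- M },
           v = { v[, , l, k] <- M },
           valid = { valid[, , l] <- M != 0 },
           topo = { topo <- structure(list(grid = grid, depth = M),
                                      class = "topography") },
           stop("malformed field file: unknown variable '", var, "'"))
    i <- i + nlat + 1L
  }
  if (any(is.na(u)) || any(is.na(v)))
    stop("malformed field file: incomplete u/v blocks")
  seed <- if (!is.null(hdr$seed) && hdr$seed != "NA")
    as.integer(hdr$seed) else NULL
  structure(list(grid = grid, topo = topo, params = NULL,
                 u = u, v = v, valid = valid, seed = seed),
            class = "velocity_field_series")
}
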