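# Fixed-kernel utilization distributions, isopleth home ranges, minimum
# convex polygons and accumulation curves.
#
# The home-range model: an animal's space use is summarized by a utilization
# distribution (UD), the probability density of finding the animal at a
# location.  The UD is estimated by a fixed bivariate Gaussian kernel with a
# diagonal bandwidth matrix chosen per axis by the Sheather-Jones direct
# plug-in method, and the "home range" is the 95% highest-density isopleth
# (the outer 5% of the UD is excluded to avoid inflating area with rarely
# used tails).

#' Construct a utilization distribution
#'
#' @param z density matrix (per square metre), row 1 = southernmost row.
#' @param cell_size cell side in metres.
#' @param origin lower-left corner `c(x0, y0)`.
#' @param bandwidth per-axis kernel bandwidths `c(h_x, h_y)` in metres.
#' @param n_points number of locations behind the estimate.
#' @param animal_id label.
#' @param renormalize rescale so total mass over the grid is exactly 1.
#' @return Object of class `ud`.
#' @export
ud <- function(z, cell_size, origin, bandwidth = c(NA_real_, NA_real_),
               n_points = NA_integer_, animal_id = NA_character_,
               renormalize = TRUE) {
  z <- as.matrix(z)
  if (any(z < 0, na.rm = TRUE)) stop("ud: negative density")
  z[is.na(z)] <- 0
  mass <- sum(z) * cell_size^2
  if (renormalize) {
    if (mass <= 0) stop("ud: zero total mass")
    z <- z / mass
  } else if (abs(mass - 1) > 1e-6) {
    warning("ud: grid mass ", signif(mass, 6), " differs from 1")
  }
  structure(
    list(z = z, cell_size = cell_size, origin = as.numeric(origin),
         bandwidth = as.numeric(bandwidth),
         n_points = n_points, animal_id = as.character(animal_id)),
    class = "ud"
  )
}

#' @export
print.ud <- function(x, ...) {
  cat("<ud> ", x$animal_id, ": ", nrow(x$z), "x", ncol(x$z), " cells @ ",
      x$cell_size, " m, h = (", signif(x$bandwidth[1], 4), ", ",
      signif(x$bandwidth[2], 4), ") m, n = ", x$n_points, "\n", sep = "")
  invisible(x)
}

ud_mass <- function(ud) sum(ud$z) * ud$cell_size^2

#' Per-axis direct plug-in kernel bandwidths
#'
#' Sheather-Jones two-stage direct plug-in selection
#' (via [stats::bw.SJ()] with `method = "dpi"`), applied independently to the
#' x and y coordinates.  The bandwidth matrix is restricted to diagonal.
#'
#' @param points a [location_set()], or a two-column matrix/data frame of
#'   coordinates in metres.
#' @return Named numeric `c(h_x, h_y)`, strictly positive, in metres.
#' @export
plug_in_bandwidth <- function(points) {
  xy <- as_xy(points)
  if (nrow(xy) < 10) {
    stop("plug_in_bandwidth: need at least 10 locations, got ", nrow(xy))
  }
  if (stats::sd(xy[, 1]) == 0 || stats::sd(xy[, 2]) == 0) {
    stop("plug_in_bandwidth: zero variance on an axis")
  }
  c(h_x = stats::bw.SJ(xy[, 1], method = "dpi"),
    h_y = stats::bw.SJ(xy[, 2], method = "dpi"))
}

as_xy <- function(points) {
  if (inherits(points, "location_set")) {
    cbind(points$points$x, points$points$y)
  } else {
    m <- as.matrix(points)[, 1:2, drop = FALSE]
    storage.mode(m) <- "double"
    m
  }
}

#' Estimate a fixed-kernel utilization distribution
#'
#' Mean of product-Gaussian kernels centred at each location, evaluated on a
#' regular grid and renormalized to unit mass.  The grid extends over the
#' point bounding box padded by `padding` times the larger bandwidth, so
#' effectively all kernel mass falls on the grid.
#'
#' Estimation requires at least `min_locations` points (default 20, the usual
#' inclusion rule for kernel home ranges); pass a smaller value explicitly to
#' override for individuals just under the rule.
#'
#' @param points a [location_set()] or two-column coordinate matrix (metres).
#' @param bandwidth `c(h_x, h_y)` in metres; default is [plug_in_bandwidth()].
#' @param cell_size grid cell side in metres (default 50).
#' @param padding grid padding in multiples of `max(bandwidth)` (default 3).
#' @param min_locations minimum number of locations required (default 20).
#' @return A [ud()] object.
#' @export
estimate_ud <- function(points, bandwidth = NULL, cell_size = 50,
                        padding = 3, min_locations = 20) {
  xy <- as_xy(points)
  id <- if (inherits(points, "location_set")) points$animal_id else NA_character_
  n <- nrow(xy)
  if (n < min_locations) {
    stop("estimate_ud: ", n, " locations for ", id,
         " is below the minimum of ", min_locations,
         " (pass min_locations explicitly to override the >=",
         min_locations, "-location rule)")
  }
  bandwidth <- bandwidth %||% plug_in_bandwidth(xy)
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0)) {
    stop("estimate_ud: bandwidths must be positive and finite")
  }
  pad <- padding * max(bandwidth)
  x0 <- min(xy[, 1]) - pad; x1 <- max(xy[, 1]) + pad
  y0 <- min(xy[, 2]) - pad; y1 <- max(xy[, 2]) + pad
  nc <- max(2L, ceiling((x1 - x0) / cell_size))
  nr <- max(2L, ceiling((y1 - y0) / cell_size))
  ctr <- cell_centres(c(x0, y0), cell_size, c(nr, nc))
  # separable product kernel: z[r, c] = (1/n) sum_i Ky[r, i] * Kx[c, i]
  Kx <- stats::dnorm(outer(ctr$x, xy[, 1], "-") / bandwidth[1]) / bandwidth[1]
  Ky <- stats::dnorm(outer(ctr$y, xy[, 2], "-") / bandwidth[2]) / bandwidth[2]
  z <- (Ky %*% t(Kx)) / n
  ud(z, cell_size, c(x0, y0), bandwidth = bandwidth, n_points = n,
     animal_id = id)
}

#' Extract an isopleth home range from a utilization distribution
#'
#' Greedy highest-density region: grid cells are ranked by density
#' (descending, ties broken by row then column) and included until the
#' cumulative probability mass first reaches `level`.  The region is kept as
#' a cell mask, so overlap integrals over it are exact sums over the
#' discrete UD.
#'
#' @param ud a [ud()] object.
#' @param level probability level in (0, 1]; 0.95 is the conventional home
#'   range, 0.50 the core area.
#' @return Object of class `home_range` with fields `level`, `mask` (logical
#'   matrix over the UD grid), `area_km2`, `mass` (probability actually
#'   enclosed), `cell_size`, `origin`, `animal_id`.
#' @export
isopleth <- function(ud, level = 0.95) {
  if (level <= 0 || level > 1) stop("isopleth: level must be in (0, 1]")
  z <- ud$z
  cell_area <- ud$cell_size^2
  ord <- order(z, decreasing = TRUE)  # column-major => (row, col) tie order
  mass <- cumsum(z[ord]) * cell_area
  if (level == 1) {
    k <- sum(z[ord] > 0)
  } else {
    k <- which(mass >= level - 1e-12)[1]
    if (is.na(k)) k <- length(ord)
  }
  mask <- matrix(FALSE, nrow(z), ncol(z))
  mask[ord[seq_len(k)]] <- TRUE
  structure(
    list(level = level, mask = mask,
         area_km2 = k * cell_area / 1e6,
         mass = if (k > 0) mass[k] else 0,
         cell_size = ud$cell_size, origin = ud$origin,
         animal_id = ud$animal_id),
    class = "home_range"
  )
}

#' @export
print.home_range <- function(x, ...) {
  cat("<home_range> ", x$animal_id, ": ", x$level * 100, "% isopleth, ",
      round(x$area_km2, 2), " km2 (", sum(x$mask), " cells)\n", sep = "")
  invisible(x)
}

# TRUE where (x, y) falls in a cell of the home-range mask.
hr_contains <- function(hr, x, y) {
  idx <- grid_index(x, y, hr$origin, hr$cell_size, dim(hr$mask))
  out <- rep(FALSE, length(x))
  ok <- !is.na(idx[, 1])
  out[ok] <- hr$mask[idx[ok, , drop = FALSE]]
  out
}

#' Minimum convex polygon home range
#'
#' Convex hull of the locations (after optionally peeling the points
#' farthest from the centroid), with area by the shoelace formula.
#'
#' @param points a [location_set()] or coordinate matrix (metres).
#' @param fraction fraction of points retained, keeping those closest to the
#'   arithmetic mean centre (1.0 = the MCP-100% of accumulation curves).
#' @return List with `vertices` (two-column matrix, counter-clockwise,
#'   closed), `area_km2`, and `n_used`.  Fewer than 3 distinct non-collinear
#'   points give area 0 with a warning.
#' @export
mcp <- function(points, fraction = 1.0) {
  xy <- as_xy(points)
  if (fraction < 1) {
    ctr <- colMeans(xy)
    d <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
    keep <- ceiling(fraction * nrow(xy))
    xy <- xy[order(d)[seq_len(keep)], , drop = FALSE]
  }
  xy_u <- unique(xy)
  if (nrow(xy_u) < 3) {
    warning("mcp: fewer than 3 distinct points; area is 0")
    return(list(vertices = xy_u, area_km2 = 0, n_used = nrow(xy)))
  }
  h <- grDevices::chull(xy_u)
  v <- xy_u[h, , drop = FALSE]
  a <- shoelace_area(v[, 1], v[, 2])
  if (a == 0) warning("mcp: collinear points; area is 0")
  list(vertices = rbind(v, v[1, , drop = FALSE]), area_km2 = a / 1e6,
       n_used = nrow(xy))
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' MCP accumulation curve
#'
#' Area of the 100% minimum convex polygon over the first k time-ordered
#' locations, for k = 3..n.  Used to judge whether the number of locations
#' was sufficient for the home range to plateau.
#'
#' @param points a [location_set()] (points are used in time order) or an
#'   ordered coordinate matrix.
#' @return Data frame with columns `k` and `area_km2`; the sequence is
#'   non-decreasing by construction.
#' @export
accumulation_curve <- function(points) {
  xy <- as_xy(points)
  n <- nrow(xy)
  if (n < 3) stop("accumulation_curve: need at least 3 locations")
  areas <- vapply(3:n, function(k) {
    suppressWarnings(mcp(xy[seq_len(k), , drop = FALSE])$area_km2)
  }, numeric(1))
  data.frame(k = 3:n, area_km2 = areas)
}

#' Summarize home-range areas by species
#'
#' Median with minimum and maximum per species.  The median (not the mean) is
#' the headline statistic because home-range size distributions in telemetry
#' samples of this size are typically skewed.
#'
#' @param areas_km2 numeric vector of per-individual home-range areas, or a
#'   list of `home_range` objects.
#' @param species character vector of species labels, one per individual
#'   (taken from the objects when `areas_km2` is a list of home ranges with
#'   a `species` field attached via names).
#' @return Data frame with columns `species`, `n`, `median_km2`, `min_km2`,
#'   `max_km2`, one row per species.
#' @export
summarize_home_ranges <- function(areas_km2, species) {
  if (is.list(areas_km2) && all(vapply(areas_km2, inherits, logical(1), "home_range"))) {
    areas_km2 <- vapply(areas_km2, `[[`, numeric(1), "area_km2")
  }
  stopifnot(length(areas_km2) == length(species))
  out <- do.call(rbind, lapply(split(areas_km2, species), function(a) {
    data.frame(n = length(a), median_km2 = stats::median(a),
               min_km2 = min(a), max_km2 = max(a))
  }))
  data.frame(species = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Apply the minimum-location inclusion rule
#'
#' @param location_counts named integer vector (or data frame column) of
#'   per-individual location counts.
#' @param min_locations threshold (default 20).
#' @return Logical vector: `TRUE` for individuals meeting the rule.
#' @export
meets_location_rule <- function(location_counts, min_locations = 20) {
  location_counts >= min_locations
}
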