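# Space-use overlap indices between animals or species.
#
# PHR(j | i): the probability of animal j being located inside animal i's
# home range, i.e. animal j's UD integrated over i's isopleth region.
# Asymmetric by nature.
#
# UDOI(i, j) = A_ij * sum over the shared region of UD_i * UD_j * cell_area,
# where A_ij is the area of the intersection of the two home ranges.  0 when
# the home ranges are disjoint, 1 for two uniform UDs overlapping
# completely, and > 1 when two non-uniform UDs concentrate use in the same
# places.  Symmetric and dimensionless (density carries 1/area).

#' Resample a utilization distribution onto another grid
#'
#' Bilinear interpolation of densities at the target cell centres (zero
#' outside the source extent), renormalized to unit mass.
#'
#' @param ud a [ud()] object.
#' @param origin,cell_size,dim target grid geometry.
#' @return A [ud()] on the target grid.
#' @export
resample_ud <- function(ud, origin, cell_size, dim) {
  ctr <- cell_centres(origin, cell_size, dim)
  xs <- rep(ctr$x, each = dim[1])
  ys <- rep(ctr$y, times = dim[2])
  z <- matrix(bilinear_at(ud$z, ud$origin, ud$cell_size, xs, ys),
              nrow = dim[1], ncol = dim[2])
  ud(z, cell_size, origin, bandwidth = ud$bandwidth,
     n_points = ud$n_points, animal_id = ud$animal_id)
}

# (x0, x1, y0, y1) extent of a gridded object (ud or home_range).
grid_extent <- function(o) {
  m <- o$z %||% o$mask
  c(o$origin[1], o$origin[1] + ncol(m) * o$cell_size,
    o$origin[2], o$origin[2] + nrow(m) * o$cell_size)
}

extents_disjoint <- function(a, b) {
  a[2] <= b[1] || b[2] <= a[1] || a[4] <= b[3] || b[4] <= a[3]
}

# Union extent of two gridded objects at the finer of their two cell sizes.
common_grid <- function(ud_i, ud_j) {
  cs <- min(ud_i$cell_size, ud_j$cell_size)
  ei <- grid_extent(ud_i); ej <- grid_extent(ud_j)
  x0 <- min(ei[1], ej[1]); x1 <- max(ei[2], ej[2])
  y0 <- min(ei[3], ej[3]); y1 <- max(ei[4], ej[4])
  list(origin = c(x0, y0), cell_size = cs,
       dim = c(ceiling((y1 - y0) / cs), ceiling((x1 - x0) / cs)))
}

same_grid <- function(a, b) {
  identical(dim(a$z %||% a$mask), dim(b$z %||% b$mask)) &&
    a$cell_size == b$cell_size && all(a$origin == b$origin)
}

#' Probability of an animal being inside another's home range (PHR)
#'
#' Integrates `ud_j` over the cells of `hr_i`.  When the two objects live on
#' different grids, `ud_j` is resampled onto `hr_i`'s grid (bilinear,
#' renormalized); disable with `resample = FALSE` to make grid mismatch an
#' error.
#'
#' @param ud_j the [ud()] of animal j.
#' @param hr_i the [isopleth()] home range of animal i.
#' @param resample allow automatic resampling onto `hr_i`'s grid.
#' @return Probability in \[0, 1\].
#' @export
phr <- function(ud_j, hr_i, resample = TRUE) {
  if (same_grid(ud_j, hr_i)) {
    return(min(1, sum(ud_j$z[hr_i$mask]) * ud_j$cell_size^2))
  }
  if (!resample) stop("phr: ud and home range are on different grids")
  if (extents_disjoint(grid_extent(ud_j), grid_extent(hr_i))) return(0)
  g <- common_grid(ud_j, hr_i)
  ud_j <- resample_ud(ud_j, g$origin, g$cell_size, g$dim)
  mask <- hr_mask_on_grid(hr_i, g)
  min(1, sum(ud_j$z[mask]) * ud_j$cell_size^2)
}

#' Utilization distribution overlap index (UDOI)
#'
#' @param ud_i,ud_j [ud()] objects.
#' @param hr_i,hr_j their [isopleth()] home ranges (defaults: 95% isopleths
#'   of `ud_i`, `ud_j`).
#' @param level isopleth level used when home ranges are not supplied.
#' @return Non-negative index; exactly 0 when the home ranges share no cell.
#' @export
udoi <- function(ud_i, ud_j, hr_i = NULL, hr_j = NULL, level = 0.95) {
  hr_i <- hr_i %||% isopleth(ud_i, level)
  hr_j <- hr_j %||% isopleth(ud_j, level)
  if (extents_disjoint(grid_extent(hr_i), grid_extent(hr_j))) return(0)
  if (!(same_grid(ud_i, ud_j) && same_grid(ud_i, hr_i) && same_grid(ud_i, hr_j))) {
    g <- common_grid(ud_i, ud_j)
    in_i <- hr_mask_on_grid(hr_i, g)
    in_j <- hr_mask_on_grid(hr_j, g)
    ud_i <- resample_ud(ud_i, g$origin, g$cell_size, g$dim)
    ud_j <- resample_ud(ud_j, g$origin, g$cell_size, g$dim)
  } else {
    in_i <- hr_i$mask; in_j <- hr_j$mask
  }
  both <- in_i & in_j
  if (!any(both)) return(0)
  cell_area <- ud_i$cell_size^2
  a_ij <- sum(both) * cell_area
  a_ij * sum(ud_i$z[both] * ud_j$z[both]) * cell_area
}

# Evaluate a home-range mask at the cell centres of another grid.
hr_mask_on_grid <- function(hr, g) {
  ctr <- cell_centres(g$origin, g$cell_size, g$dim)
  xs <- rep(ctr$x, each = g$dim[1])
  ys <- rep(ctr$y, times = g$dim[2])
  matrix(hr_contains(hr, xs, ys), nrow = g$dim[1], ncol = g$dim[2])
}

#' Pairwise PHR / UDOI overlap matrix
#'
#' Builds one UD per group (species by default, pooling all locations of a
#' species' individuals; or per individual) and computes all pairwise
#' overlap indices on a shared grid.  PHR is reported as a percentage, with
#' `phr[i, j]` the probability of group j's UD mass falling inside group i's
#' home range — so the diagonal equals the isopleth level.
#'
#' @param locations list of [location_set()] objects.
#' @param level isopleth level for the home ranges (default 0.95).
#' @param by `"species"` (pool individuals) or `"individual"`.
#' @param cell_size UD grid cell size in metres.
#' @param min_locations groups with fewer pooled locations are skipped with
#'   a warning.
#' @param bandwidths optional named list of `c(h_x, h_y)` per group label,
#'   overriding plug-in selection.
#' @return Object of class `overlap_matrix`: list with `labels`, `phr`
#'   (percent, rows = home-range owner i, cols = animal j), `udoi`
#'   (symmetric), `level`, and `uds` (the fitted UDs).
#' @export
species_overlap_matrix <- function(locations, level = 0.95, by = "species",
                                   cell_size = 50, min_locations = 20,
                                   bandwidths = NULL) {
  by <- match.arg(by, c("species", "individual"))
  key <- vapply(locations, function(l) {
    if (by == "species") l$species else l$animal_id
  }, character(1))
  groups <- split(locations, key)
  pooled <- lapply(groups, function(g) {
    do.call(rbind, lapply(g, function(l) cbind(l$points$x, l$points$y)))
  })
  enough <- vapply(pooled, nrow, integer(1)) >= min_locations
  if (any(!enough)) {
    warning("species_overlap_matrix: skipping ",
            paste(names(pooled)[!enough], collapse = ", "),
            " (fewer than ", min_locations, " pooled locations)")
  }
  pooled <- pooled[enough]
  labels <- names(pooled)
  if (length(labels) == 0) stop("species_overlap_matrix: no usable groups")

  # shared grid across all groups keeps the pairwise integrals resampling-free
  hs <- lapply(labels, function(lb) {
    bandwidths[[lb]] %||% plug_in_bandwidth(pooled[[lb]])
  })
  names(hs) <- labels
  all_xy <- do.call(rbind, pooled)
  pad <- 3 * max(unlist(hs))
  extent <- c(min(all_xy[, 1]) - pad, max(all_xy[, 1]) + pad,
              min(all_xy[, 2]) - pad, max(all_xy[, 2]) + pad)
  uds <- lapply(labels, function(lb) {
    estimate_ud_on(pooled[[lb]], hs[[lb]], cell_size, extent, animal_id = lb)
  })
  names(uds) <- labels
  hrs <- lapply(uds, isopleth, level = level)

  k <- length(labels)
  phr_m <- matrix(NA_real_, k, k, dimnames = list(owner = labels, visitor = labels))
  udoi_m <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    phr_m[i, j] <- 100 * phr(uds[[j]], hrs[[i]])
    if (j >= i) {
      udoi_m[i, j] <- udoi(uds[[i]], uds[[j]], hrs[[i]], hrs[[j]])
      udoi_m[j, i] <- udoi_m[i, j]
    }
  }
  structure(list(labels = labels, phr = phr_m, udoi = udoi_m, level = level,
                 uds = uds, home_ranges = hrs),
            class = "overlap_matrix")
}

# Kernel UD on an explicitly supplied extent (shared-grid variant of
# estimate_ud; same kernel arithmetic).
estimate_ud_on <- function(xy, bandwidth, cell_size, extent, animal_id) {
  nc <- max(2L, ceiling((extent[2] - extent[1]) / cell_size))
  nr <- max(2L, ceiling((extent[4] - extent[3]) / cell_size))
  ctr <- cell_centres(c(extent[1], extent[3]), cell_size, c(nr, nc))
  Kx <- stats::dnorm(outer(ctr$x, xy[, 1], "-") / bandwidth[1]) / bandwidth[1]
  Ky <- stats::dnorm(outer(ctr$y, xy[, 2], "-") / bandwidth[2]) / bandwidth[2]
  z <- (Ky %*% t(Kx)) / nrow(xy)
  ud(z, cell_size, c(extent[1], extent[3]), bandwidth = bandwidth,
     n_points = nrow(xy), animal_id = animal_id)
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("<overlap_matrix> level ", x$level * 100, "%: PHR % (rows = home-range",
      " owner), UDOI in parentheses\n", sep = "")
  k <- length(x$labels)
  disp <- matrix("", k, k, dimnames = dimnames(x$phr))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    disp[i, j] <- sprintf("%.1f (%.2f)", x$phr[i, j], x$udoi[i, j])
  }
  print(disp, quote = FALSE)
  invisible(x)
}

#' Write an overlap matrix as CSV
#'
#' One row per ordered pair with PHR (%) and UDOI columns.
#'
#' @param x an `overlap_matrix`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_overlap_csv <- function(x, path) {
  k <- length(x$labels)
  rows <- expand.grid(owner = x$labels, visitor = x$labels,
                      stringsAsFactors = FALSE)
  rows$phr_pct <- as.vector(x$phr)
  rows$udoi <- as.vector(x$udoi)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
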