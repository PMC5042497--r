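# Shared raster-grid conventions.
#
# All gridded objects (habitat maps, utilization distributions, home-range
# masks) use the same layout: a matrix `z` with row 1 the southernmost row,
# `origin = c(x0, y0)` the lower-left corner of cell [1, 1], square cells of
# side `cell_size` metres, and half-open cell membership
# [x0 + (c-1)*cs, x0 + c*cs).  Coordinates are planar projected metres (e.g.
# UTM); the package performs no geodetic transforms.

#' Map planar coordinates to grid row/column indices
#'
#' Uses the package-wide half-open cell convention; points on the upper or
#' right boundary of the grid fall outside it.
#'
#' @param x,y numeric vectors of coordinates (metres).
#' @param origin length-2 numeric, lower-left corner of the grid.
#' @param cell_size cell side in metres.
#' @param dim grid dimension `c(nrow, ncol)` (rows run south to north).
#' @return A two-column integer matrix of (row, col); `NA` for points outside
#'   the grid extent.
#' @keywords internal
grid_index <- function(x, y, origin, cell_size, dim) {
  col <- floor((x - origin[1]) / cell_size) + 1L
  row <- floor((y - origin[2]) / cell_size) + 1L
  bad <- row < 1L | row > dim[1] | col < 1L | col > dim[2] |
    !is.finite(x) | !is.finite(y)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Coordinates of cell centres
#'
#' @param origin,cell_size,dim grid geometry as in [grid_index()].
#' @return List with vectors `x` (length ncol) and `y` (length nrow) of cell
#'   centre coordinates.
#' @keywords internal
cell_centres <- function(origin, cell_size, dim) {
  list(
    x = origin[1] + (seq_len(dim[2]) - 0.5) * cell_size,
    y = origin[2] + (seq_len(dim[1]) - 0.5) * cell_size
  )
}

# Bilinear interpolation of a grid field at arbitrary points, treating the
# field as samples at cell centres and 0 outside the outermost centres.
bilinear_at <- function(z, origin, cell_size, x, y) {
  nr <- nrow(z); nc <- ncol(z)
  gx <- (x - (origin[1] + 0.5 * cell_size)) / cell_size  # 0-based col coord
  gy <- (y - (origin[2] + 0.5 * cell_size)) / cell_size
  c0 <- floor(gx); r0 <- floor(gy)
  fx <- gx - c0; fy <- gy - r0
  val <- numeric(length(x))
  # corner weights; out-of-range corners contribute 0
  corner <- function(r, c) {
    ok <- r >= 0 & r < nr & c >= 0 & c < nc
    v <- numeric(length(x))
    v[ok] <- z[cbind(r[ok] + 1L, c[ok] + 1L)]
    v
  }
  val <- corner(r0, c0) * (1 - fx) * (1 - fy) +
    corner(r0, c0 + 1) * fx * (1 - fy) +
    corner(r0 + 1, c0) * (1 - fx) * fy +
    corner(r0 + 1, c0 + 1) * fx * fy
  val
}

#' Test points against a polygon (ray casting)
#'
#' Even-odd rule; points exactly on an edge may fall on either side, which is
#' immaterial at the cell sizes used here.
#'
#' @param x,y point coordinates.
#' @param px,py polygon vertex coordinates (closed implicitly).
#' @return Logical vector.
#' @keywords internal
point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
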