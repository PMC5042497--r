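# Readers and writers for the external artifacts the pipeline touches:
# telemetry tables, camera-trap records, categorical habitat maps
# (ESRI ASCII grid or GeoJSON polygons), and utilization-distribution grids.
# All delimited files are comma-separated UTF-8 with a mandatory header.

#' Read telemetry locations into per-animal location sets
#'
#' Parses a delimited telemetry table (one row per radio-location) and splits
#' it into one `location_set` per animal, time-sorted.  Rows with unparseable
#' coordinates or timestamps are dropped, each with a logged reason
#' (see the `rejections` attribute).
#'
#' @param path path to a comma-delimited file with a header row.
#' @param schema named list mapping the fields `animal_id`, `species`, `x`,
#'   `y`, `timestamp` (and optionally `habitat`, `active`) to column names in
#'   the file.  Defaults to those literal names.
#' @param time_format a [strptime()] format for the timestamp column, or
#'   `NULL` to accept ISO-8601 (`"%Y-%m-%d %H:%M:%S"` / `"%Y-%m-%dT%H:%M:%S"`,
#'   with date-only rows allowed).
#' @return A named list of `location_set` objects (one per animal), with
#'   attribute `rejections`: a data frame of dropped rows and reasons.
#'   Each `location_set` has fields `animal_id`, `species`, and `points`
#'   (a data frame with `x`, `y`, `t`, and optional `habitat`, `active`).
#' @export
read_locations <- function(path, schema = NULL, time_format = NULL) {
  defaults <- list(animal_id = "animal_id", species = "species",
                   x = "x", y = "y", timestamp = "timestamp",
                   habitat = "habitat", active = "active")
  schema <- utils::modifyList(defaults, as.list(schema %||% list()))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("animal_id", "species", "x", "y", "timestamp")
  missing_cols <- vapply(mandatory, function(f) !(schema[[f]] %in% names(raw)),
                         logical(1))
  if (any(missing_cols)) {
    stop("telemetry file ", path, " lacks mandatory column(s): ",
         paste(unlist(schema[mandatory][missing_cols]), collapse = ", "))
  }

  x <- suppressWarnings(as.numeric(raw[[schema$x]]))
  y <- suppressWarnings(as.numeric(raw[[schema$y]]))
  t <- parse_timestamp(raw[[schema$timestamp]], time_format)
  reason <- rep(NA_character_, nrow(raw))
  reason[!is.finite(x) | !is.finite(y)] <- "unparseable coordinate"
  reason[is.na(t) & is.na(reason)] <- "unparseable timestamp"

  keep <- is.na(reason)
  rejections <- data.frame(row = which(!keep), reason = reason[!keep],
                           stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rejections))) {
    message("read_locations: dropped row ", rejections$row[i], " (",
            rejections$reason[i], ")")
  }

  df <- data.frame(
    animal_id = as.character(raw[[schema$animal_id]])[keep],
    species = as.character(raw[[schema$species]])[keep],
    x = x[keep], y = y[keep], t = t[keep],
    stringsAsFactors = FALSE
  )
  if (schema$habitat %in% names(raw)) df$habitat <- as.character(raw[[schema$habitat]])[keep]
  if (schema$active %in% names(raw)) df$active <- as.logical(raw[[schema$active]])[keep]

  sets <- lapply(split(df, df$animal_id), function(d) {
    d <- d[order(d$t), , drop = FALSE]
    location_set(animal_id = d$animal_id[1], species = d$species[1],
                 x = d$x, y = d$y, t = d$t,
                 habitat = d$habitat, active = d$active)
  })
  structure(sets, rejections = rejections)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_timestamp <- function(s, time_format = NULL) {
  s <- as.character(s)
  if (!is.null(time_format)) {
    return(as.POSIXct(s, format = time_format, tz = "UTC"))
  }
  t <- as.POSIXct(s, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  iso_t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  t[is.na(t)] <- iso_t[is.na(t)]
  date_only <- is.na(t) & grepl("^\\d{4}-\\d{2}-\\d{2}$", s)
  t[date_only] <- as.POSIXct(s[date_only], format = "%Y-%m-%d", tz = "UTC")
  t
}

#' Construct a location set
#'
#' The atomic input to home-range and habitat-selection analyses: one
#' animal's timestamped planar locations (projected metres).
#'
#' @param animal_id,species labels.
#' @param x,y numeric coordinates in projected metres.
#' @param t timestamps (`POSIXct`), strictly increasing.
#' @param habitat optional per-point habitat class labels.
#' @param active optional per-point logical activity flags.
#' @return An object of class `location_set`.
#' @export
location_set <- function(animal_id, species, x, y, t,
                         habitat = NULL, active = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(t))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("location_set: non-finite coordinates for animal ", animal_id)
  }
  if (is.unsorted(t, strictly = FALSE)) {
    stop("location_set: timestamps must be non-decreasing for animal ", animal_id)
  }
  points <- data.frame(x = x, y = y, t = t)
  if (!is.null(habitat)) points$habitat <- habitat
  if (!is.null(active)) points$active <- active
  structure(
    list(animal_id = as.character(animal_id), species = as.character(species),
         points = points),
    class = "location_set"
  )
}

#' @export
print.location_set <- function(x, ...) {
  cat("<location_set> ", x$animal_id, " (", x$species, "): ",
      nrow(x$points), " locations, ",
      format(min(x$points$t)), " to ", format(max(x$points$t)), "\n", sep = "")
  invisible(x)
}

#' @export
print.habitat_map <- function(x, ...) {
  p <- habitat_proportions(x)
  cat("<habitat_map> ", nrow(x$codes), "x", ncol(x$codes), " cells @ ",
      x$cell_size, " m\n  classes: ",
      paste(sprintf("%s (%.2f)", names(p), p), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Construct a categorical habitat map
#'
#' @param codes integer matrix of 1-based class codes (row 1 = southernmost
#'   row); `NA` marks nodata cells.
#' @param cell_size cell side in metres.
#' @param origin lower-left corner `c(x0, y0)`.
#' @param classes character vector of habitat class names; `codes` index it.
#' @return An object of class `habitat_map`.
#' @export
habitat_map <- function(codes, cell_size, origin, classes) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (length(classes) < 1) stop("habitat_map: need at least one class")
  rng <- range(codes, na.rm = TRUE)
  if (rng[1] < 1L || rng[2] > length(classes)) {
    stop("habitat_map: cell codes must index the class list (1..",
         length(classes), ")")
  }
  structure(
    list(codes = codes, cell_size = cell_size,
         origin = as.numeric(origin), classes = as.character(classes)),
    class = "habitat_map"
  )
}

#' Habitat class proportions over non-nodata cells
#'
#' @param map a `habitat_map`.
#' @return Named numeric vector of class proportions, summing to 1.
#' @export
habitat_proportions <- function(map) {
  counts <- tabulate(map$codes[!is.na(map$codes)], nbins = length(map$classes))
  p <- counts / sum(counts)
  names(p) <- map$classes
  p
}

#' Habitat class at point coordinates
#'
#' @param map a `habitat_map`.
#' @param x,y coordinates in metres.
#' @return Character vector of class names (`NA` outside the map or on
#'   nodata cells).
#' @export
habitat_at <- function(map, x, y) {
  idx <- grid_index(x, y, map$origin, map$cell_size, dim(map$codes))
  code <- rep(NA_integer_, length(x))
  ok <- !is.na(idx[, 1])
  code[ok] <- map$codes[idx[ok, , drop = FALSE]]
  map$classes[code]
}

#' Read a categorical habitat map
#'
#' Accepts either an ESRI ASCII grid (`.asc`) with an accompanying legend CSV
#' (`code,name`), or a GeoJSON FeatureCollection of polygons carrying a
#' `habitat` property, rasterized at `cell_size` by cell-centre membership.
#'
#' @param path path to an `.asc` or `.geojson`/`.json` file.
#' @param legend path to the legend CSV (required for ASCII grids).
#' @param cell_size rasterization cell size in metres (GeoJSON input only).
#' @param classes optional class ordering; defaults to the legend order (ASCII)
#'   or sorted unique habitat properties (GeoJSON).
#' @return A [habitat_map()].
#' @export
read_habitat_map <- function(path, legend = NULL, cell_size = NULL,
                             classes = NULL) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    read_habitat_geojson(path, cell_size = cell_size, classes = classes)
  } else {
    if (is.null(legend)) stop("read_habitat_map: ASCII grid needs a legend CSV")
    leg <- utils::read.csv(legend, stringsAsFactors = FALSE)
    if (!all(c("code", "name") %in% names(leg))) {
      stop("legend must have columns 'code' and 'name'")
    }
    g <- read_ascii_grid(path)
    codes <- g$z
    known <- codes %in% leg$code | is.na(codes)
    if (!all(known)) {
      stop("habitat grid contains code(s) not in legend: ",
           paste(unique(codes[!known]), collapse = ", "),
           "; legend codes: ", paste(leg$code, collapse = ", "))
    }
    cls <- classes %||% leg$name
    recode <- match(leg$name, cls)[match(codes, leg$code)]
    habitat_map(matrix(recode, nrow(codes), ncol(codes)),
                cell_size = g$cell_size, origin = g$origin, classes = cls)
  }
}

read_habitat_geojson <- function(path, cell_size, classes = NULL) {
  if (is.null(cell_size)) stop("GeoJSON habitat input needs a cell_size")
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  polys <- list()
  for (f in feats) {
    hab <- f$properties$habitat
    if (is.null(hab)) stop("GeoJSON feature lacks a 'habitat' property")
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
      stop("unsupported geometry type: ", geom$type)
    )
    for (ring in rings) {
      m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      polys[[length(polys) + 1L]] <- list(habitat = hab, x = m[, 1], y = m[, 2])
    }
  }
  habs <- vapply(polys, `[[`, character(1), "habitat")
  cls <- classes %||% sort(unique(habs))
  if (!all(habs %in% cls)) {
    stop("unknown habitat label(s): ", paste(setdiff(habs, cls), collapse = ", "),
         "; known: ", paste(cls, collapse = ", "))
  }
  xr <- range(unlist(lapply(polys, `[[`, "x")))
  yr <- range(unlist(lapply(polys, `[[`, "y")))
  origin <- c(xr[1], yr[1])
  nc <- max(1L, ceiling((xr[2] - xr[1]) / cell_size))
  nr <- max(1L, ceiling((yr[2] - yr[1]) / cell_size))
  ctr <- cell_centres(origin, cell_size, c(nr, nc))
  xs <- rep(ctr$x, each = nr); ys <- rep(ctr$y, times = nc)
  codes <- rep(NA_integer_, nr * nc)
  for (p in polys) {  # later features overwrite earlier ones where they overlap
    inside <- point_in_polygon(xs, ys, p$x, p$y)
    codes[inside] <- match(p$habitat, cls)
  }
  habitat_map(matrix(codes, nr, nc), cell_size, origin, cls)
}

# ESRI ASCII grid primitives (row 1 of the file is the northernmost row;
# internally row 1 is the southernmost).
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (!is.null(hdr$dx) && !is.null(hdr$dy) && hdr$dx != hdr$dy) {
    stop("non-square cells are not supported")
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) stop("ASCII grid size mismatch in ", path)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  z <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  z <- z[nr:1, , drop = FALSE]  # flip to south-first rows
  x0 <- hdr$xllcorner %||% (hdr$xllcenter - hdr$cellsize / 2)
  y0 <- hdr$yllcorner %||% (hdr$yllcenter - hdr$cellsize / 2)
  list(z = z, cell_size = hdr$cellsize, origin = c(x0, y0))
}

write_ascii_grid <- function(z, cell_size, origin, path, nodata = -9999,
                             digits = 7) {
  nr <- nrow(z); nc <- ncol(z)
  out <- z[nr:1, , drop = FALSE]  # north-first rows in the file
  out[is.na(out)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", sprintf("%.15g", origin[1])),
    paste("yllcorner", sprintf("%.15g", origin[2])),
    paste("cellsize", format(cell_size, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  for (r in seq_len(nr)) {
    writeLines(paste(formatC(out[r, ], format = "g", digits = digits),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Write a utilization distribution as an ESRI ASCII grid
#'
#' Densities are written with 7 significant digits so a write/read round trip
#' reproduces them to at least 6.
#'
#' @param ud a [ud()] object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_ud_grid <- function(ud, path) {
  write_ascii_grid(ud$z, ud$cell_size, ud$origin, path)
}

#' Read a utilization distribution from an ESRI ASCII grid
#'
#' @param path path to an `.asc` file written by [write_ud_grid()].
#' @param animal_id optional label to attach.
#' @return A [ud()] object (bandwidth and point count unknown: `NA`).
#' @export
read_ud_grid <- function(path, animal_id = NA_character_) {
  g <- read_ascii_grid(path)
  ud(g$z, g$cell_size, g$origin, bandwidth = c(NA_real_, NA_real_),
     n_points = NA_integer_, animal_id = animal_id, renormalize = FALSE)
}

#' Write a habitat map as an ESRI ASCII grid plus legend CSV
#'
#' @param map a [habitat_map()].
#' @param path output `.asc` path.
#' @param legend output legend CSV path (`code,name`).
#' @return The grid path, invisibly.
#' @export
write_habitat_map <- function(map, path, legend) {
  write_ascii_grid(map$codes, map$cell_size, map$origin, path, digits = 12)
  utils::write.csv(
    data.frame(code = seq_along(map$classes), name = map$classes),
    legend, row.names = FALSE
  )
  invisible(path)
}

#' Read camera-trap records
#'
#' @param path comma-delimited file with header columns `station_id`,
#'   `species`, `datetime` (ISO-8601 unless `time_format` is given).
#' @param time_format optional [strptime()] format for `datetime`.
#' @return Data frame with columns `station_id`, `species`, `datetime`;
#'   unparseable rows are dropped with a message.
#' @export
read_camera_records <- function(path, time_format = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "species", "datetime")
  if (!all(need %in% names(raw))) {
    stop("camera file must have columns: ", paste(need, collapse = ", "))
  }
  t <- parse_timestamp(raw$datetime, time_format)
  bad <- is.na(t)
  if (any(bad)) {
    message("read_camera_records: dropped ", sum(bad),
            " row(s) with unparseable datetime")
  }
  data.frame(station_id = as.character(raw$station_id)[!bad],
             species = as.character(raw$species)[!bad],
             datetime = t[!bad], stringsAsFactors = FALSE)
}
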