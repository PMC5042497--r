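# Diel activity patterns on sun-adjusted circular time.
#
# Detection clock times are first rescaled to "sun time": sunrise is
# anchored at 06:00 and sunset at 18:00, with the light and dark periods
# each divided into 12 equal hours (double anchoring).  This removes
# seasonal day-length variation so records pooled across seasons remain
# comparable.  Activity is then a density on the 24-h circle, estimated by
# a von Mises kernel (the circular analogue of the Gaussian, with
# concentration kappa as the smoothing parameter).  Active periods are the
# 95% and 50% highest-density isopleths of that density, and between-species
# overlap is the shared fraction of those isopleth intervals.

# ---- solar geometry ---------------------------------------------------------

#' Sunrise and sunset for a site and date
#'
#' Standard NOAA solar-position equations (solar zenith 90.833 degrees for
#' the refracted upper limb), accurate to about two minutes against
#' published calculators.
#'
#' @param latitude,longitude degrees (south and west negative);
#'   `abs(latitude)` must be below 66.5 (no polar day/night handling).
#' @param date a `Date` (or string coercible to one).
#' @param utc_offset hours to add to UTC for local clock time (e.g. -4 for
#'   the western Brazilian Pantanal).
#' @return Object of class `sun_clock`: `date`, `sunrise`, `sunset` (decimal
#'   clock hours), `latitude`, `longitude`, `utc_offset`.
#' @export
solar_times <- function(latitude, longitude, date, utc_offset = 0) {
  if (abs(latitude) >= 66.5) {
    stop("solar_times: polar latitudes are not supported")
  }
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j"))
  # fractional year (radians), mid-day
  g <- 2 * pi / 365 * (doy - 1 + 0.5)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g)
                      - 0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  lat <- latitude * pi / 180
  zen <- 90.833 * pi / 180
  cos_ha <- (cos(zen) - sin(lat) * sin(decl)) / (cos(lat) * cos(decl))
  if (cos_ha > 1 || cos_ha < -1) {
    stop("solar_times: sun does not rise/set on ", format(date),
         " at latitude ", latitude)
  }
  ha <- acos(cos_ha) * 180 / pi  # degrees
  # minutes UTC
  sunrise_utc <- 720 - 4 * (longitude + ha) - eqtime
  sunset_utc <- 720 - 4 * (longitude - ha) - eqtime
  structure(
    list(date = date,
         sunrise = ((sunrise_utc / 60 + utc_offset) %% 24),
         sunset = ((sunset_utc / 60 + utc_offset) %% 24),
         latitude = latitude, longitude = longitude, utc_offset = utc_offset),
    class = "sun_clock"
  )
}

#' @export
print.sun_clock <- function(x, ...) {
  fmt <- function(h) sprintf("%02d:%02d", floor(h), round((h %% 1) * 60))
  cat("<sun_clock> ", format(x$date), " @ (", x$latitude, ", ", x$longitude,
      "): sunrise ", fmt(x$sunrise), ", sunset ", fmt(x$sunset), "\n", sep = "")
  invisible(x)
}

#' Convert clock time to sun time (double anchoring)
#'
#' Piecewise-linear rescaling: sunrise maps to 06:00 and sunset to 18:00;
#' daytime is stretched/compressed linearly between those anchors and night
#' is mapped linearly onto (18:00, 30:00) mod 24.  On a 12-h day the map is
#' the identity.  For each date the map is a strictly increasing circular
#' bijection, inverted by [sun_adjust_inverse()].
#'
#' @param clock_time decimal clock hours in \[0, 24).
#' @param sun a [solar_times()] `sun_clock`.
#' @return Sun time in \[0, 24).
#' @export
sun_adjust <- function(clock_time, sun) {
  sr <- sun$sunrise; ss <- sun$sunset
  day_len <- ss - sr
  night_len <- 24 - day_len
  t <- clock_time %% 24
  is_day <- t >= sr & t < ss
  out <- numeric(length(t))
  out[is_day] <- 6 + 12 * (t[is_day] - sr) / day_len
  # hours since sunset, with pre-sunrise times wrapped past midnight
  since_ss <- (t[!is_day] - ss) %% 24
  out[!is_day] <- (18 + 12 * since_ss / night_len) %% 24
  out
}

#' Inverse of the sun-time map
#'
#' @param sun_time sun hours in \[0, 24).
#' @param sun a `sun_clock`.
#' @return Clock hours in \[0, 24) such that
#'   `sun_adjust(result, sun) == sun_time`.
#' @export
sun_adjust_inverse <- function(sun_time, sun) {
  sr <- sun$sunrise; ss <- sun$sunset
  day_len <- ss - sr
  night_len <- 24 - day_len
  s <- sun_time %% 24
  is_day <- s >= 6 & s < 18
  out <- numeric(length(s))
  out[is_day] <- sr + (s[is_day] - 6) / 12 * day_len
  since_18 <- (s[!is_day] - 18) %% 24
  out[!is_day] <- (ss + since_18 / 12 * night_len) %% 24
  out
}

#' Sun-adjust camera-trap records
#'
#' Computes each record's date-specific sunrise/sunset and maps its clock
#' time to sun time.
#'
#' @param records data frame as from [read_camera_records()].
#' @param latitude,longitude site coordinates (degrees).
#' @param utc_offset hours; timestamps are taken as local clock time.
#' @return The data frame with an added `sun_time` column.
#' @export
sun_adjust_records <- function(records, latitude, longitude, utc_offset = 0) {
  dt <- records$datetime
  dates <- as.Date(dt, tz = "UTC")
  hours <- as.numeric(dt - as.POSIXct(dates, tz = "UTC"), units = "hours")
  sun_time <- numeric(nrow(records))
  for (d in unique(dates)) {
    sel <- dates == d
    sun <- solar_times(latitude, longitude, as.Date(d, origin = "1970-01-01"),
                       utc_offset = utc_offset)
    sun_time[sel] <- sun_adjust(hours[sel], sun)
  }
  records$sun_time <- sun_time
  records
}

# ---- circular kernel density ------------------------------------------------

# von Mises kernel values, overflow-safe for large kappa.
vm_kernel <- function(delta, kappa) {
  exp(kappa * (cos(delta) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Circular kernel density of diel activity
#'
#' Mean of von Mises kernels centred at each observation on the 24-h circle.
#' When `kappa` is not supplied it is selected by maximizing the
#' leave-one-out log-likelihood over the grid 2^0, 2^1, ..., 2^10.
#'
#' @param sun_times numeric vector of sun times in \[0, 24); at least 10.
#' @param kappa optional fixed von Mises concentration.
#' @param m number of evaluation points around the circle (default 1440,
#'   one per sun-minute).
#' @param species optional label.
#' @return Object of class `circular_density`: `hours` (m values in
#'   \[0, 24)), `density` (per sun-hour; integrates to 1 over the circle),
#'   `kappa`, `n`, `species`.
#' @export
circular_kde <- function(sun_times, kappa = NULL, m = 1440, species = NA_character_) {
  n <- length(sun_times)
  if (n < 10) stop("circular_kde: need at least 10 observations, got ", n)
  theta <- (sun_times %% 24) * 2 * pi / 24
  if (is.null(kappa)) {
    grid <- 2^(0:10)
    if (stats::sd(theta) == 0) {
      warning("circular_kde: all observations identical; using the largest ",
              "grid kappa")
      kappa <- max(grid)
    } else {
      D <- outer(theta, theta, "-")
      ll <- vapply(grid, function(k) {
        K <- vm_kernel(D, k)
        diag(K) <- 0
        loo <- rowSums(K) / (n - 1)
        sum(log(pmax(loo, 1e-300)))
      }, numeric(1))
      kappa <- grid[which.max(ll)]
    }
  }
  hours <- seq(0, 24, length.out = m + 1)[-(m + 1)]
  phi <- hours * 2 * pi / 24
  dens_angle <- rowMeans(vm_kernel(outer(phi, theta, "-"), kappa))
  density <- dens_angle * 2 * pi / 24  # per sun-hour
  density <- density / (mean(density) * 24)  # discrete unit mass
  structure(list(hours = hours, density = density, kappa = kappa, n = n,
                 species = as.character(species)),
            class = "circular_density")
}

#' @export
print.circular_density <- function(x, ...) {
  cat("<circular_density> ", x$species, ": n = ", x$n, ", kappa = ", x$kappa,
      ", mode at ", sprintf("%.1f", x$hours[which.max(x$density)]),
      " sun-h\n", sep = "")
  invisible(x)
}

#' Highest-density activity isopleth
#'
#' Accumulates the highest-density minutes of the circle until the requested
#' probability mass is reached, then merges contiguous runs (wrapping
#' midnight) into intervals.
#'
#' @param d a [circular_kde()] density.
#' @param level probability level (0.95 = active period, 0.50 = core
#'   activity).
#' @return Object of class `activity_isopleth`: `level`, `mask` (logical
#'   over the m grid minutes), `intervals` (data frame `start`, `end` in
#'   sun-hours; `end` < `start` marks a midnight wrap), `total_duration`
#'   (sun-hours).
#' @export
activity_isopleth <- function(d, level = 0.95) {
  if (level <= 0 || level > 1) stop("activity_isopleth: level must be in (0, 1]")
  m <- length(d$density)
  w <- d$density * 24 / m  # probability mass per grid minute
  ord <- order(d$density, decreasing = TRUE)
  k <- which(cumsum(w[ord]) >= level - 1e-12)[1]
  if (is.na(k)) k <- m
  mask <- rep(FALSE, m)
  mask[ord[seq_len(k)]] <- TRUE

  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  iv <- data.frame(start = d$hours[starts[runs$values]],
                   end = (d$hours[ends[runs$values]] + 24 / m) %% 24)
  if (nrow(iv) > 1 && mask[1] && mask[m]) {  # merge the midnight wrap
    iv$start[1] <- iv$start[nrow(iv)]
    iv <- iv[-nrow(iv), , drop = FALSE]
  }
  structure(list(level = level, mask = mask,
                 intervals = iv,
                 total_duration = sum(mask) * 24 / m),
            class = "activity_isopleth")
}

#' Overlap between two activity isopleths
#'
#' Shared active time as a percentage.  The symmetric index is
#' 100 * |a intersect b| / |a union b|; the directed indices normalize the
#' intersection by each isopleth's own duration.
#'
#' @param a,b [activity_isopleth()]s at the same level.
#' @return List `overlap_pct` (symmetric), `of_a_pct`, `of_b_pct`
#'   (directed), `intersection_h`, `union_h`.
#' @export
activity_overlap <- function(a, b) {
  if (a$level != b$level) {
    stop("activity_overlap: isopleths are at different levels")
  }
  if (length(a$mask) != length(b$mask)) {
    stop("activity_overlap: isopleths use different grids")
  }
  m <- length(a$mask)
  inter <- sum(a$mask & b$mask) * 24 / m
  uni <- sum(a$mask | b$mask) * 24 / m
  list(overlap_pct = if (uni > 0) 100 * inter / uni else 0,
       of_a_pct = if (a$total_duration > 0) 100 * inter / a$total_duration else 0,
       of_b_pct = if (b$total_duration > 0) 100 * inter / b$total_duration else 0,
       intersection_h = inter, union_h = uni)
}

#' Pairwise activity-overlap matrix across species
#'
#' Fits a circular kernel density per species and reports the symmetric
#' isopleth overlap percentage for every pair.
#'
#' @param records data frame with `species` and `sun_time` columns (see
#'   [sun_adjust_records()]).
#' @param level isopleth level (default 0.95).
#' @param min_records species with fewer records are skipped with a warning.
#' @param kappa optional fixed kappa applied to all species.
#' @return List with `overlap` (symmetric percent matrix, 100 on the
#'   diagonal), `densities`, `isopleths`.
#' @export
activity_overlap_matrix <- function(records, level = 0.95, min_records = 10,
                                    kappa = NULL) {
  splits <- split(records$sun_time, records$species)
  enough <- vapply(splits, length, integer(1)) >= min_records
  if (any(!enough)) {
    warning("activity_overlap_matrix: skipping ",
            paste(names(splits)[!enough], collapse = ", "),
            " (fewer than ", min_records, " records)")
  }
  splits <- splits[enough]
  dens <- lapply(names(splits), function(sp) {
    circular_kde(splits[[sp]], kappa = kappa, species = sp)
  })
  names(dens) <- names(splits)
  isos <- lapply(dens, activity_isopleth, level = level)
  k <- length(dens)
  ov <- matrix(100, k, k, dimnames = list(names(dens), names(dens)))
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      ov[i, j] <- ov[j, i] <- activity_overlap(isos[[i]], isos[[j]])$overlap_pct
    }
  }
  list(overlap = ov, densities = dens, isopleths = isos)
}

# ---- camera-trap summaries --------------------------------------------------

#' Summarize camera-trap records by species
#'
#' @param records data frame with a `species` column (one row per photo
#'   record), or a named vector of per-species record counts.
#' @param trap_days total sampling effort in camera trap-days (optional;
#'   enables the capture-success column).
#' @return Data frame with `species`, `records`, `pct` (percent of all
#'   records, one decimal), and `per_100_trap_days` when effort is given;
#'   sorted by decreasing record count.  Empty input gives an empty table.
#' @export
camera_summary <- function(records, trap_days = NULL) {
  counts <- if (is.data.frame(records)) {
    table(records$species)
  } else {
    as.table(records)
  }
  if (length(counts) == 0 || sum(counts) == 0) {
    return(data.frame(species = character(), records = integer(),
                      pct = numeric()))
  }
  out <- data.frame(species = names(counts),
                    records = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$pct <- round(100 * out$records / sum(out$records), 1)
  if (!is.null(trap_days)) {
    out$per_100_trap_days <- round(100 * out$records / trap_days, 1)
  }
  out[order(-out$records), , drop = FALSE]
}
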