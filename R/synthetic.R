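# Seeded simulator with known ground truth for every analysis stage:
# patchy categorical landscapes, habitat-weighted telemetry with bivariate
# normal home ranges, von Mises mixture activity times, and camera-trap
# detections thinned by activity.  All generators are pure functions of
# (config, seed), so parameter-recovery tests need no external data.
#
# Ground truth exposed per individual/species:
#   * analytic 95% home-range ellipse area pi * q * sqrt(det(Sigma)), with
#     q the 0.95 quantile of chi-squared on 2 df;
#   * the selection weight vector behind the location density
#     f(x) proportional to N(x; mu, Sigma) * w[habitat(x)];
#   * the true activity density (von Mises mixture).

#' Build and validate a simulation configuration
#'
#' @param seed master seed (integer).
#' @param landscape list: `size` (cells per side), `cell_size` (m),
#'   `classes` (D names), `proportions` (target class proportions, sum 1),
#'   `patchiness` (Gaussian smoothing scale in cells; 0 = iid cells).
#' @param individuals list of lists: `species`, `animal_id`, `centre`
#'   (c(x, y) m), `sigma` (2x2 covariance, m^2), `weights` (D positive
#'   selection weights), `n_locations`.
#' @param activity named list (per species) of von Mises mixtures: each a
#'   list with `mean_hour`, `kappa`, `weight` vectors (weights sum to 1).
#' @param camera list: `n_stations`, `survey_days`, `daily_rate` (expected
#'   detections per species per station-day), `start_date`.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, landscape = NULL, individuals = list(),
                       activity = list(), camera = NULL) {
  landscape <- utils::modifyList(list(
    size = 200, cell_size = 50,
    classes = c("forest", "savanna", "scrub-savanna", "grassland", "ponds"),
    proportions = c(0.30, 0.30, 0.15, 0.15, 0.10),
    patchiness = 6
  ), as.list(landscape %||% list()))
  if (abs(sum(landscape$proportions) - 1) > 1e-8) {
    stop("sim_config: landscape proportions must sum to 1")
  }
  if (length(landscape$proportions) != length(landscape$classes)) {
    stop("sim_config: one target proportion per class required")
  }
  for (ind in individuals) {
    sig <- ind$sigma
    if (!isTRUE(all.equal(sig, t(sig))) || any(eigen(sig, only.values = TRUE)$values <= 0)) {
      stop("sim_config: sigma must be symmetric positive definite for ",
           ind$animal_id)
    }
    if (any(ind$weights <= 0)) {
      stop("sim_config: selection weights must be positive for ", ind$animal_id)
    }
  }
  for (sp in names(activity)) {
    mix <- activity[[sp]]
    if (abs(sum(mix$weight) - 1) > 1e-8) {
      stop("sim_config: activity mixture weights for ", sp, " must sum to 1")
    }
    if (any(mix$kappa < 0)) stop("sim_config: kappa must be >= 0 for ", sp)
  }
  camera <- utils::modifyList(list(
    n_stations = 36, survey_days = 60, daily_rate = 0.5,
    start_date = as.Date("2006-01-01")
  ), as.list(camera %||% list()))
  structure(list(seed = as.integer(seed), landscape = landscape,
                 individuals = individuals, activity = activity,
                 camera = camera),
            class = "sim_config")
}

#' Generate a patchy categorical landscape
#'
#' A white-noise field is smoothed by circular convolution with a Gaussian
#' kernel of standard deviation `patchiness` cells and thresholded at the
#' target quantiles, so realized class proportions are exact up to cell
#' rounding while spatial patch size grows with the smoothing scale.
#' `patchiness = 0` gives iid cells.
#'
#' @param cfg a [sim_config()].
#' @return A [habitat_map()] with origin (0, 0).
#' @export
generate_landscape <- function(cfg) {
  ls <- cfg$landscape
  set.seed(cfg$seed)
  n <- ls$size
  d <- length(ls$classes)
  if (d == 1) {
    return(habitat_map(matrix(1L, n, n), ls$cell_size, c(0, 0), ls$classes))
  }
  field <- matrix(stats::rnorm(n * n), n, n)
  if (ls$patchiness > 0) {
    # circular convolution with an isotropic Gaussian via FFT
    ix <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k1 <- exp(-ix^2 / (2 * ls$patchiness^2))
    K <- outer(k1, k1)
    K <- K / sum(K)
    field <- Re(stats::fft(stats::fft(field) * stats::fft(K), inverse = TRUE)) / (n * n)
  }
  br <- stats::quantile(field, probs = cumsum(ls$proportions)[-d])
  codes <- matrix(findInterval(field, br) + 1L, n, n)
  habitat_map(codes, ls$cell_size, c(0, 0), ls$classes)
}

#' Generate one individual's habitat-weighted telemetry
#'
#' Locations are drawn from f(x) proportional to
#' N(x; centre, sigma) * w\[habitat(x)\] by rejection sampling: bivariate
#' normal proposals, accepted with probability w/max(w) (proposals falling
#' off the map are rejected outright).  With equal weights the locations are
#' exactly bivariate normal; with unequal weights the expected
#' use-vs-availability log-ratios are known.  Timestamps advance one per
#' simulated day at a uniformly drawn hour, mirroring daily radio-fixes.
#'
#' @param ind one entry of `cfg$individuals` (see [sim_config()]).
#' @param map a [habitat_map()].
#' @param seed seed for this individual's draws.
#' @param start_date first fix date.
#' @return A [location_set()] with per-point habitat labels; ground truth is
#'   attached as attribute `truth` (list: `centre`, `sigma`, `weights`,
#'   `ellipse95_km2`).
#' @export
generate_individual <- function(ind, map, seed,
                                start_date = as.Date("2006-01-01")) {
  set.seed(seed)
  n <- ind$n_locations
  w <- ind$weights / max(ind$weights)
  ev <- eigen(ind$sigma)
  A <- ev$vectors %*% diag(sqrt(ev$values), 2)
  pts <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(pts) < n) {
    batch <- max(200L, 4L * (n - nrow(pts)))
    z <- matrix(stats::rnorm(2 * batch), 2)
    prop <- t(ind$centre + A %*% z)
    cls <- habitat_at(map, prop[, 1], prop[, 2])
    code <- match(cls, map$classes)
    keep <- !is.na(code) & stats::runif(batch) < w[ifelse(is.na(code), 1L, code)]
    pts <- rbind(pts, prop[keep, , drop = FALSE])
    tries <- tries + batch
    if (tries > 2000L && nrow(pts) / tries < 1e-3) {
      stop("generate_individual: acceptance rate below 1e-3 for ",
           ind$animal_id, "; enlarge the map or soften the weights")
    }
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  t <- as.POSIXct(start_date, tz = "UTC") + (seq_len(n) - 1) * 86400 +
    round(stats::runif(n, 0, 86399))
  loc <- location_set(ind$animal_id, ind$species, pts[, 1], pts[, 2], t,
                      habitat = habitat_at(map, pts[, 1], pts[, 2]),
                      active = rep(TRUE, n))
  attr(loc, "truth") <- list(
    centre = ind$centre, sigma = ind$sigma, weights = ind$weights,
    ellipse95_km2 = true_ellipse_area(ind$sigma) / 1e6
  )
  loc
}

#' Analytic 95% home-range ellipse area of a bivariate normal
#'
#' pi * q * sqrt(det(sigma)) with q the 0.95 chi-squared(2 df) quantile;
#' the truth against which kernel home-range areas are checked.
#'
#' @param sigma 2x2 covariance (m^2).
#' @param level probability level (default 0.95).
#' @return Area in square metres.
#' @export
true_ellipse_area <- function(sigma, level = 0.95) {
  pi * stats::qchisq(level, df = 2) * sqrt(det(sigma))
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; kappa = 0 gives the circular
#' uniform.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return Angles in \[0, 2*pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("rvonmises: kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    take <- sum(ok)
    out[got + seq_len(take)] <- (th + mu) %% (2 * pi)
    got <- got + take
  }
  out
}

#' Generate activity times from a species' von Mises mixture
#'
#' @param mixture list with vectors `mean_hour`, `kappa`, `weight`.
#' @param n number of draws.
#' @param seed seed.
#' @return Sun times in \[0, 24).
#' @export
generate_activity_times <- function(mixture, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(mixture$weight), n, replace = TRUE,
                     prob = mixture$weight)
  th <- numeric(n)
  for (k in unique(comp)) {
    sel <- comp == k
    th[sel] <- rvonmises(sum(sel), mixture$mean_hour[k] * 2 * pi / 24,
                         mixture$kappa[k])
  }
  th * 24 / (2 * pi)
}

#' True activity density of a von Mises mixture
#'
#' @param mixture list with `mean_hour`, `kappa`, `weight`.
#' @param m evaluation points around the circle (default 1440).
#' @return A `circular_density` (per sun-hour, unit mass) for use as ground
#'   truth in recovery tests.
#' @export
true_activity_density <- function(mixture, m = 1440) {
  hours <- seq(0, 24, length.out = m + 1)[-(m + 1)]
  phi <- hours * 2 * pi / 24
  dens <- rep(0, m)
  for (k in seq_along(mixture$weight)) {
    dens <- dens + mixture$weight[k] *
      vm_kernel(phi - mixture$mean_hour[k] * 2 * pi / 24, mixture$kappa[k])
  }
  density <- dens * 2 * pi / 24
  density <- density / (mean(density) * 24)
  structure(list(hours = hours, density = density, kappa = NA_real_,
                 n = NA_integer_, species = "truth"),
            class = "circular_density")
}

#' Generate camera-trap detection records
#'
#' Per species, the number of detections is Poisson with mean
#' `daily_rate * n_stations * survey_days`, and detection sun-times follow
#' the species' activity mixture (a thinned Poisson stream whose diel
#' intensity is proportional to the activity density).  Sun times are
#' converted back to clock times through the date-specific solar map, so
#' the records exercise the full sun-adjustment round trip.
#'
#' @param cfg a [sim_config()] (uses `cfg$camera` and `cfg$activity`).
#' @param latitude,longitude site coordinates for the solar conversion.
#' @param utc_offset hours.
#' @param seed seed (default `cfg$seed`).
#' @return Data frame with `station_id`, `species`, `datetime`; attribute
#'   `trap_days` records the total effort.
#' @export
generate_camera_records <- function(cfg, latitude = -18.98, longitude = -56.65,
                                    utc_offset = -4, seed = NULL) {
  set.seed(seed %||% cfg$seed)
  cam <- cfg$camera
  recs <- list()
  for (sp in names(cfg$activity)) {
    n <- stats::rpois(1, cam$daily_rate * cam$n_stations * cam$survey_days)
    if (n == 0) next
    sun_times <- generate_activity_times(cfg$activity[[sp]], n)
    day <- sample.int(cam$survey_days, n, replace = TRUE) - 1L
    station <- sprintf("S%02d", sample.int(cam$n_stations, n, replace = TRUE))
    dates <- as.Date(cam$start_date) + day
    clock <- numeric(n)
    for (d in unique(dates)) {
      sel <- dates == d
      sun <- solar_times(latitude, longitude, as.Date(d, origin = "1970-01-01"),
                         utc_offset = utc_offset)
      clock[sel] <- sun_adjust_inverse(sun_times[sel], sun)
    }
    recs[[sp]] <- data.frame(
      station_id = station, species = sp,
      datetime = as.POSIXct(dates, tz = "UTC") + round(clock * 3600),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(station_id = character(), species = character(),
               datetime = as.POSIXct(character(), tz = "UTC"))
  rownames(out) <- NULL
  out <- out[order(out$datetime), , drop = FALSE]
  attr(out, "trap_days") <- cam$n_stations * cam$survey_days
  out
}

#' Simulate a full study: landscape, telemetry, cameras
#'
#' @param cfg a [sim_config()].
#' @return List with `map`, `locations` (list of [location_set()]s with
#'   truth attributes), `camera` (record data frame), and `truth` (named
#'   list per individual plus `activity` mixtures).
#' @export
simulate_study <- function(cfg) {
  map <- generate_landscape(cfg)
  locations <- list()
  truth <- list()
  for (i in seq_along(cfg$individuals)) {
    ind <- cfg$individuals[[i]]
    loc <- generate_individual(ind, map, seed = cfg$seed + i)
    locations[[ind$animal_id]] <- loc
    truth[[ind$animal_id]] <- attr(loc, "truth")
  }
  camera <- generate_camera_records(cfg, seed = cfg$seed + 10000L)
  list(map = map, locations = locations, camera = camera,
       truth = c(truth, list(activity = cfg$activity)))
}
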