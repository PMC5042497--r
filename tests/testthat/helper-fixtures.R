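# Shared fixtures, built in code at test time.

# Bivariate-normal location set in projected metres.
make_normal_points <- function(n, centre = c(0, 0), sd = c(500, 500),
                               seed = 1, id = "A1", species = "sp") {
  set.seed(seed)
  location_set(id, species,
               x = rnorm(n, centre[1], sd[1]),
               y = rnorm(n, centre[2], sd[2]),
               t = as.POSIXct("2006-01-01", tz = "UTC") + seq_len(n) * 86400)
}

# Uniform UD over an interior block of a grid, plus its full-support
# home range.
make_uniform_ud <- function(origin = c(0, 0), n = 40, block = 11:30,
                            cell_size = 1, id = "U") {
  z <- matrix(0, n, n)
  z[block, block] <- 1
  u <- ud(z, cell_size, origin, animal_id = id)
  list(ud = u, hr = isopleth(u, 1.0))
}

# Analytic standard-bivariate-normal UD sampled on a fine grid
# (sigma in the same length units as cell_size).
make_gaussian_ud <- function(sigma = 1, cell_size = 0.05, half_width = 5) {
  g <- seq(-half_width + cell_size / 2, half_width - cell_size / 2,
           by = cell_size)
  z <- outer(dnorm(g, sd = sigma), dnorm(g, sd = sigma))  # rows = y
  ud(z, cell_size, c(-half_width, -half_width), animal_id = "gauss")
}

# Small flat-key landscape config for simulator tests.
make_sim_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, ...)
}

# Composition records with a prescribed per-habitat selection effect:
# individual log-ratio differences are effect + iid noise.
make_comps <- function(n, effect, habitats = paste0("h", seq_along(effect)),
                       sd = 0.1, seed = 1, design = "III") {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lr <- effect + rnorm(length(effect), sd = sd)
    use <- exp(lr) / sum(exp(lr))
    avail <- rep(1 / length(effect), length(effect))
    composition_record(paste0("ind", i), use, avail, habitats, design)
  })
}

# Rayleigh test p-value for circular uniformity (independent oracle).
rayleigh_p <- function(theta) {
  n <- length(theta)
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  z <- n * rbar^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

circ_mean_hour <- function(hours) {
  th <- hours * 2 * pi / 24
  (atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi)) * 24 / (2 * pi)
}

# Activity isopleth built directly from sun-hour intervals (for interval
# arithmetic tests); intervals may wrap midnight.
make_interval_isopleth <- function(intervals, level = 0.95, m = 1440) {
  hours <- seq(0, 24, length.out = m + 1)[-(m + 1)]
  mask <- rep(FALSE, m)
  for (iv in intervals) {
    if (iv[1] <= iv[2]) {
      mask <- mask | (hours >= iv[1] & hours < iv[2])
    } else {
      mask <- mask | hours >= iv[1] | hours < iv[2]
    }
  }
  structure(list(level = level, mask = mask, intervals = NULL,
                 total_duration = sum(mask) * 24 / m),
            class = "activity_isopleth")
}
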