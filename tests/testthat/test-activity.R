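test_that("solar times follow the expected geometry", {
  # equator at an equinox: roughly 06:00 / 18:00 local solar time, i.e.
  # symmetric about solar noon (clock noon differs by the equation of time)
  eq <- solar_times(0, 0, as.Date("2006-03-20"))
  noon <- (eq$sunrise + eq$sunset) / 2
  expect_lt(abs((noon - eq$sunrise) - 6), 10 / 60)
  expect_lt(abs((eq$sunset - noon) - 6), 10 / 60)
  expect_lt(abs(noon - 12), 20 / 60)  # equation of time stays under 17 min

  # southern-hemisphere site near the December solstice: long days
  s <- solar_times(-18.98, -56.65, as.Date("2006-12-21"), utc_offset = -4)
  expect_gt(s$sunset - s$sunrise, 12)
  # and short days in June
  w <- solar_times(-18.98, -56.65, as.Date("2006-06-21"), utc_offset = -4)
  expect_lt(w$sunset - w$sunrise, 12)

  for (d in c("2006-01-15", "2006-04-10", "2006-08-01", "2006-11-05")) {
    sc <- solar_times(-18.98, -56.65, as.Date(d), utc_offset = -4)
    noon <- (sc$sunrise + sc$sunset) / 2
    expect_true(sc$sunrise < noon && noon < sc$sunset)
  }
  expect_error(solar_times(70, 0, as.Date("2006-06-21")), "polar")
})

test_that("sun adjustment double-anchors sunrise and sunset", {
  even <- list(sunrise = 6, sunset = 18)
  expect_equal(sun_adjust(12, even), 12)              # identity on a 12-h day
  expect_equal(sun_adjust(c(0, 3, 21), even), c(0, 3, 21))

  sun <- list(sunrise = 5, sunset = 19)
  expect_equal(sun_adjust(8, sun), 6 + 12 * 3 / 14)   # 8.571 sun-hours
  expect_equal(sun_adjust(5, sun), 6)                 # sunrise anchor
  expect_equal(sun_adjust(19, sun), 18)               # sunset anchor
  # night side: midnight sits 5 clock-hours into a 10-h night
  expect_equal(sun_adjust(0, sun), (18 + 12 * 5 / 10) %% 24)

  # circular bijection: strictly increasing (mod 24) and invertible
  clock <- seq(0, 23.9, by = 0.1)
  st <- sun_adjust(clock, sun)
  unwrapped <- st + 24 * cumsum(c(0, diff(st) < 0))
  expect_true(all(diff(unwrapped) > 0))
  expect_equal(sun_adjust_inverse(st, sun), clock, tolerance = 1e-9)
})

test_that("circular kernel densities integrate to 1 and recover known shapes", {
  set.seed(8)
  unif <- runif(2000, 0, 24)
  d_u <- circular_kde(unif)
  expect_equal(mean(d_u$density) * 24, 1, tolerance = 1e-6)
  expect_lt(max(abs(d_u$density - 1 / 24)), 0.01)

  tm <- generate_activity_times(list(mean_hour = 2, kappa = 8, weight = 1),
                                2000, seed = 10)
  d <- circular_kde(tm)
  mode <- d$hours[which.max(d$density)]
  circ_dist <- min(abs(mode - 2), 24 - abs(mode - 2))
  expect_lt(circ_dist, 0.25)
  expect_equal(mean(d$density) * 24, 1, tolerance = 1e-6)

  expect_error(circular_kde(runif(5, 0, 24)), "at least 10")
  expect_warning(circular_kde(rep(3, 50)), "identical")
})

test_that("activity isopleths are minimal highest-density interval sets", {
  set.seed(9)
  d_u <- circular_kde(runif(3000, 0, 24), kappa = 1)
  iso50 <- activity_isopleth(d_u, 0.5)
  expect_equal(iso50$total_duration, 12, tolerance = 0.5)

  tm <- generate_activity_times(list(mean_hour = 14, kappa = 6, weight = 1),
                                1000, seed = 11)
  d <- circular_kde(tm)
  i95 <- activity_isopleth(d, 0.95)
  i50 <- activity_isopleth(d, 0.50)
  expect_true(all(i95$mask[i50$mask]))                 # nesting
  expect_equal(nrow(i50$intervals), 1)                 # unimodal -> one interval
  mode <- d$hours[which.max(d$density)]
  expect_true(i50$intervals$start < mode && mode < i50$intervals$end)
  expect_gte(sum(d$density[i95$mask]) * 24 / length(d$density), 0.95)

  # wrapping a mode across midnight still yields one (wrapped) interval
  tmw <- generate_activity_times(list(mean_hour = 0, kappa = 6, weight = 1),
                                 1000, seed = 12)
  iw <- activity_isopleth(circular_kde(tmw), 0.5)
  expect_equal(nrow(iw$intervals), 1)
  expect_gt(iw$intervals$start, iw$intervals$end)      # midnight wrap encoding
})

test_that("isopleth overlap follows interval arithmetic", {
  a <- make_interval_isopleth(list(c(0, 12)))
  b <- make_interval_isopleth(list(c(6, 18)))
  ov <- activity_overlap(a, b)
  expect_equal(ov$overlap_pct, 100 * 6 / 18, tolerance = 0.01)
  expect_equal(ov$of_a_pct, 50, tolerance = 0.01)

  expect_equal(activity_overlap(a, a)$overlap_pct, 100)
  dis <- make_interval_isopleth(list(c(13, 20)))
  expect_equal(activity_overlap(a, dis)$overlap_pct, 0)
  expect_error(activity_overlap(a, make_interval_isopleth(list(c(0, 6)),
                                                          level = 0.5)),
               "different levels")
})

test_that("rotating all observations shifts isopleths but not overlap", {
  t1 <- generate_activity_times(list(mean_hour = 3, kappa = 5, weight = 1),
                                400, seed = 14)
  t2 <- generate_activity_times(list(mean_hour = 9, kappa = 5, weight = 1),
                                400, seed = 15)
  base <- activity_overlap(activity_isopleth(circular_kde(t1, kappa = 32), 0.95),
                           activity_isopleth(circular_kde(t2, kappa = 32), 0.95))
  delta <- 5.25
  rot <- activity_overlap(
    activity_isopleth(circular_kde((t1 + delta) %% 24, kappa = 32), 0.95),
    activity_isopleth(circular_kde((t2 + delta) %% 24, kappa = 32), 0.95))
  expect_equal(rot$overlap_pct, base$overlap_pct, tolerance = 0.02)
})

test_that("camera summaries reproduce the published record shares", {
  counts <- pantanal_camera_counts()
  tab <- camera_summary(setNames(counts$records, counts$species),
                        trap_days = pantanal_trap_days())
  expect_equal(sum(tab$records), 1773)
  expect_equal(tab$pct[tab$species == "crab-eating fox"], 66.3)
  expect_equal(round(tab$pct[tab$species == "crab-eating fox"]), 66)
  expect_equal(round(tab$pct[tab$species == "brown-nosed coati"]), 24)
  expect_equal(tab$per_100_trap_days[tab$species == "crab-eating fox"],
               round(100 * 1176 / 2238, 1))
  empty <- camera_summary(data.frame(species = character()))
  expect_equal(nrow(empty), 0)
})

test_that("known von Mises mixtures are recovered end to end", {
  mix1 <- list(mean_hour = c(6, 18), kappa = c(3, 3), weight = c(0.5, 0.5))
  mix2 <- list(mean_hour = 0, kappa = 2, weight = 1)
  truth <- activity_overlap(
    activity_isopleth(true_activity_density(mix1), 0.95),
    activity_isopleth(true_activity_density(mix2), 0.95))$overlap_pct
  est <- vapply(1:12, function(r) {
    s1 <- generate_activity_times(mix1, 400, seed = 500 + r)
    s2 <- generate_activity_times(mix2, 400, seed = 800 + r)
    activity_overlap(activity_isopleth(circular_kde(s1), 0.95),
                     activity_isopleth(circular_kde(s2), 0.95))$overlap_pct
  }, numeric(1))
  expect_lt(abs(median(est) - truth), 5)
})
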