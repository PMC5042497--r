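test_that("landscape generation hits target proportions and is seed-stable", {
  one <- sim_config(seed = 1, landscape = list(size = 20, classes = "forest",
                                               proportions = 1))
  m1 <- generate_landscape(one)
  expect_true(all(m1$codes == 1L))

  cfg <- sim_config(seed = 11, landscape = list(
    size = 100, classes = LETTERS[1:5], proportions = rep(0.2, 5),
    patchiness = 0))
  map <- generate_landscape(cfg)
  expect_true(all(abs(habitat_proportions(map) - 0.2) < 0.03))

  patchy <- sim_config(seed = 11, landscape = list(
    size = 100, classes = LETTERS[1:5], proportions = c(0.4, 0.3, 0.15, 0.1, 0.05),
    patchiness = 5))
  pm <- generate_landscape(patchy)
  expect_true(all(abs(habitat_proportions(pm) -
                        patchy$landscape$proportions) < 0.03))
  expect_identical(generate_landscape(patchy)$codes, pm$codes)

  expect_error(sim_config(landscape = list(proportions = c(0.5, 0.2),
                                           classes = c("a", "b"))),
               "sum to 1")
})

test_that("habitat-weighted locations are unbiased with equal weights", {
  cfg <- sim_config(seed = 2, landscape = list(size = 120, cell_size = 50,
                                               patchiness = 4))
  map <- generate_landscape(cfg)
  ind <- list(species = "fox", animal_id = "F1", centre = c(3000, 3000),
              sigma = diag(c(300^2, 300^2)), weights = rep(1, 5),
              n_locations = 500)
  loc <- generate_individual(ind, map, seed = 9)
  xy <- cbind(loc$points$x, loc$points$y)
  expect_equal(nrow(xy), 500)
  expect_true(all(!is.na(habitat_at(map, xy[, 1], xy[, 2]))))
  se <- 300 / sqrt(500)
  expect_lt(abs(mean(xy[, 1]) - 3000), 3 * se)
  expect_lt(abs(mean(xy[, 2]) - 3000), 3 * se)
  # daily cadence: one fix per simulated day, strictly ordered
  expect_true(all(diff(as.Date(loc$points$t)) == 1))
  # truth accessor matches the closed-form ellipse area
  expect_equal(attr(loc, "truth")$ellipse95_km2,
               pi * qchisq(0.95, 2) * 300^2 / 1e6)
})

test_that("a favoured habitat is used above its availability", {
  cfg <- sim_config(seed = 5, landscape = list(size = 120, cell_size = 50,
                                               proportions = rep(0.2, 5),
                                               patchiness = 3))
  map <- generate_landscape(cfg)
  avail <- habitat_proportions(map)[1]
  hits <- vapply(1:20, function(r) {
    ind <- list(species = "fox", animal_id = "F1", centre = c(3000, 3000),
                sigma = diag(c(800^2, 800^2)), weights = c(2, 1, 1, 1, 1),
                n_locations = 300)
    loc <- generate_individual(ind, map, seed = 100 + r)
    mean(loc$points$habitat == map$classes[1]) > avail
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("activity-time draws recover the mixture and respect the seed", {
  mix <- list(mean_hour = 2, kappa = 8, weight = 1)
  tm <- generate_activity_times(mix, 1e4, seed = 3)
  expect_true(all(tm >= 0 & tm < 24))
  expect_lt(abs(circ_mean_hour(tm) - 2), 0.05)
  expect_identical(generate_activity_times(mix, 1e4, seed = 3), tm)

  # kappa = 0 is circular-uniform: Rayleigh test should rarely reject
  nonsig <- vapply(1:100, function(r) {
    u <- generate_activity_times(list(mean_hour = 0, kappa = 0, weight = 1),
                                 100, seed = r)
    rayleigh_p(u * 2 * pi / 24) > 0.05
  }, logical(1))
  expect_gte(mean(nonsig), 0.9)
})

test_that("camera records form a thinned Poisson stream with activity-shaped times", {
  cfg <- sim_config(
    seed = 8,
    activity = list(day = list(mean_hour = 12, kappa = 4, weight = 1),
                    night = list(mean_hour = 0, kappa = 4, weight = 1)),
    camera = list(n_stations = 10, survey_days = 30, daily_rate = 1))
  rec <- generate_camera_records(cfg)
  lambda <- 10 * 30 * 1
  counts <- table(rec$species)
  expect_true(all(abs(counts - lambda) < 3 * sqrt(lambda)))
  expect_identical(generate_camera_records(cfg), rec)

  none <- sim_config(seed = 8,
                     activity = list(day = list(mean_hour = 12, kappa = 4,
                                                weight = 1)),
                     camera = list(n_stations = 10, survey_days = 30,
                                   daily_rate = 0))
  expect_equal(nrow(generate_camera_records(none)), 0)
})

test_that("disjoint activity windows give near-zero recovered overlap", {
  cfg <- sim_config(
    seed = 13,
    activity = list(day = list(mean_hour = 12, kappa = 12, weight = 1),
                    night = list(mean_hour = 0, kappa = 12, weight = 1)),
    camera = list(n_stations = 12, survey_days = 30, daily_rate = 0.9))
  rec <- generate_camera_records(cfg)
  rec <- sun_adjust_records(rec, -18.98, -56.65, utc_offset = -4)
  ov <- activity_overlap_matrix(rec, level = 0.95)
  expect_lt(ov$overlap["day", "night"], 10)
})
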