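test_that("zero replacement substitutes and renormalizes, else is a no-op", {
  r <- composition_record("i1", c(0.5, 0.5, 0), c(1, 1, 1) / 3, c("a", "b", "c"))
  z <- zero_replace(r, 1e-4)
  expect_equal(sum(z$use), 1)
  expect_equal(unname(z$use[3]), 1e-4 / (1 + 1e-4))
  expect_equal(unname(z$use[1]), 0.5 / (1 + 1e-4))
  expect_identical(zero_replace(r, 1e-4)$avail, r$avail)  # no zeros in avail

  r2 <- composition_record("i2", c(1, 0, 0), c(1, 1, 1) / 3, c("a", "b", "c"))
  expect_equal(sum(zero_replace(r2)$use), 1)
  expect_error(zero_replace(r, 0), "positive")
})

test_that("Type II compositions: use in home range vs study-area availability", {
  # 50/50 A/B landscape split at x = 1000; HRs as direct cell masks
  codes <- matrix(rep(c(1L, 2L), each = 10), 20, 20, byrow = TRUE)
  map <- habitat_map(codes, 100, c(0, 0), c("A", "B"))  # A west, B east
  mk_hr <- function(cols) {
    mask <- matrix(FALSE, 20, 20); mask[6:15, cols] <- TRUE
    structure(list(level = 0.95, mask = mask, area_km2 = sum(mask) * 0.01,
                   mass = 0.95, cell_size = 100, origin = c(0, 0),
                   animal_id = "x"), class = "home_range")
  }
  hrs <- list(i1 = mk_hr(2:5), i2 = mk_hr(3:6))      # both fully in A
  comps <- composition_type2(hrs, map)
  expect_length(comps, 2)
  expect_equal(unname(comps[[1]]$use), c(1, 0))
  # availability identical across individuals, matches the hull contents
  expect_identical(comps[[1]]$avail, comps[[2]]$avail)
  expect_gt(comps[[1]]$avail["A"], 0.9)  # hull of A-side ranges stays in A

  # all-one-class landscape: use == avail, log-ratio differences are 0
  map1 <- habitat_map(matrix(1L, 20, 20), 100, c(0, 0), "A")
  c1 <- composition_type2(hrs, map1)
  expect_equal(c1[[1]]$use, c1[[1]]$avail)
  expect_error(composition_type2(hrs[1], map), "at least 2")
})

test_that("Type II proportions agree with Monte-Carlo point sampling", {
  cfg <- sim_config(seed = 17, landscape = list(size = 60, cell_size = 50,
                                                patchiness = 3))
  map <- generate_landscape(cfg)
  mask <- matrix(FALSE, 60, 60); mask[10:40, 15:45] <- TRUE
  hr <- structure(list(level = 0.95, mask = mask, area_km2 = 1, mass = 0.95,
                       cell_size = 50, origin = c(0, 0), animal_id = "m"),
                  class = "home_range")
  comps <- composition_type2(list(m = hr, m2 = hr), map)
  set.seed(99)
  xs <- runif(2e5, 15 * 50 - 50, 45 * 50)  # bounding box of the mask
  ys <- runif(2e5, 10 * 50 - 50, 40 * 50)
  keep <- nichekit:::hr_contains(hr, xs, ys)
  mc <- table(factor(habitat_at(map, xs[keep], ys[keep]),
                     levels = map$classes))
  mc <- as.numeric(mc / sum(mc))
  expect_true(all(abs(unname(comps[[1]]$use) - mc) < 0.01))
})

test_that("Type III compositions: locations vs in-range availability", {
  codes <- t(matrix(rep(c(1L, 2L), c(12, 8)), 20, 20))  # 60/40 forest/savanna
  map <- habitat_map(codes, 100, c(0, 0), c("forest", "savanna"))
  mask <- matrix(TRUE, 20, 20)
  hr <- structure(list(level = 0.95, mask = mask, area_km2 = 4, mass = 0.95,
                       cell_size = 100, origin = c(0, 0), animal_id = "F1"),
                  class = "home_range")
  set.seed(3)
  loc <- location_set("F1", "fox", x = runif(30, 0, 1190), y = runif(30, 0, 1990),
                      t = as.POSIXct("2006-01-01", tz = "UTC") + 1:30 * 86400)
  cm <- composition_type3(loc, hr, map)
  expect_equal(unname(cm$use), c(1, 0))          # all points in forest columns
  expect_equal(unname(cm$avail), c(0.6, 0.4))
  # counts conserve
  expect_equal(sum(cm$use) * 30, 30)

  out <- location_set("F1", "fox", x = c(loc$points$x, -500),
                      y = c(loc$points$y, -500),
                      t = c(loc$points$t, max(loc$points$t) + 86400))
  expect_warning(cm2 <- composition_type3(out, hr, map), "rejected 1")
  expect_equal(unname(cm2$use), c(1, 0))
  expect_error(composition_type3(loc, hr, map, min_locations = 40), "below")
})

test_that("Wilks' lambda test matches its defining identities", {
  comps <- make_comps(8, effect = c(1.2, 0, -0.4, 0.2, 0), sd = 0.3, seed = 5)
  res <- wilks_test(comps)
  expect_true(res$lambda > 0 && res$lambda <= 1)
  expect_equal(res$chi2, -res$n * log(res$lambda), tolerance = 1e-9)
  expect_equal(res$df, 4)

  # reference-habitat invariance of lambda
  res_ref <- wilks_test(comps, reference = "h2")
  expect_equal(res_ref$lambda, res$lambda, tolerance = 1e-9)

  # randomization: full sign-flip enumeration at N <= 10, strong effect -> small p
  res_r <- wilks_test(comps, mode = "both", seed = 1)
  expect_lt(res_r$p_randomization, 0.05)
  expect_gte(res_r$p_randomization, 2^-8)  # enumeration floor

  # null data: lambda near 1, parametric p not extreme
  null_comps <- make_comps(10, effect = rep(0, 5), sd = 0.3, seed = 6)
  expect_gt(wilks_test(null_comps)$p_parametric, 0.01)

  expect_error(wilks_test(comps[1:3]), "at least")
  zero_comp <- composition_record("z", c(0.5, 0.5, 0, 0, 0), rep(0.2, 5),
                                  paste0("h", 1:5))
  expect_error(wilks_test(c(comps[-1], list(zero_comp))), "zero_replace")
})

test_that("printed lambda/N pairs reproduce their chi-square statistics", {
  # published triples: (lambda, N, printed chi2); chi2 = -N ln(lambda)
  triples <- list(c(0.340, 6, 6.473), c(0.111, 6, 13.206),
                  c(0.092, 7, 16.635), c(0.192, 7, 11.539),
                  c(0.650, 7, 3.021), c(0.698, 7, 2.515))
  for (tr in triples) {
    expect_lt(abs(-tr[2] * log(tr[1]) - tr[3]), 0.15)
  }
})

test_that("the chi-square reference has its known finite-sample size", {
  # -N ln(lambda) is only asymptotically chi-squared; for a one-sample
  # MANOVA its null law is exactly monotone in Hotelling's T2, so the true
  # rejection rate at nominal 0.05 has the closed form below (0.090 at
  # N = 20, D = 5).  The simulation must match that exact value, which is
  # why the randomization mode exists for small N.
  p <- 4; n <- 20
  f_crit <- (n - p) / p * (exp(qchisq(0.95, p) / n) - 1)
  exact_size <- 1 - pf(f_crit, p, n - p)
  expect_equal(exact_size, 0.0904, tolerance = 0.01)
  set.seed(2024)
  rej <- mean(replicate(500, {
    y <- matrix(rnorm(n * p), n, p)
    pchisq(-n * log(nichekit:::wilks_lambda(y)), df = p,
           lower.tail = FALSE) < 0.05
  }))
  expect_lt(abs(rej - exact_size), 0.04)
})

test_that("the sign-flip randomization test is valid under a skewed null", {
  # symmetric-about-zero but non-normal individual effects
  set.seed(31)
  rej <- mean(replicate(120, {
    y <- matrix(rexp(8 * 3) * sample(c(-1, 1), 24, replace = TRUE), 8, 3)
    comps <- lapply(1:8, function(i) {
      use <- exp(c(y[i, ], 0)) / sum(exp(c(y[i, ], 0)))
      composition_record(paste0("i", i), use, rep(0.25, 4),
                         c("a", "b", "c", "d"))
    })
    wilks_test(comps, mode = "randomization")$p_randomization < 0.05
  }))
  expect_lte(rej, 0.05 + 0.05)  # 0.02 band plus Monte-Carlo slack at 120 sims
})

test_that("ranking matrices are antisymmetric with coherent ranks and t stats", {
  comps <- make_comps(7, effect = c(2, 1, 0.5, -0.5, -2),
                      habitats = c("savanna", "grasslands", "scrub savanna",
                                   "lakes", "forest"),
                      sd = 0.2, seed = 9)
  rm <- ranking_matrix(comps)
  expect_equal(rm$mean_diff, -t(rm$mean_diff))
  expect_equal(sort(unname(rm$rank)), 0:4)  # a permutation absent ties
  expect_equal(unname(rm$rank[c("savanna", "grasslands", "scrub savanna",
                                "lakes", "forest")]),
               c(4, 3, 2, 1, 0))

  # t statistic agrees with a brute-force paired t on the raw differences
  lr <- t(vapply(comps, function(cm) log(cm$use) - log(cm$avail), numeric(5)))
  d12 <- lr[, 1] - lr[, 2]
  expect_equal(unname(rm$stat[1, 2]),
               mean(d12) / (sd(d12) / sqrt(length(d12))), tolerance = 1e-9)
  expect_equal(unname(rm$p[1, 2]), t.test(d12)$p.value, tolerance = 1e-9)

  # degenerate pair: zero variance flagged
  same <- lapply(1:4, function(i) {
    composition_record(paste0("s", i), c(0.4, 0.4, 0.2), rep(1 / 3, 3),
                       c("a", "b", "c"))
  })
  rm2 <- ranking_matrix(same)
  expect_true(is.nan(rm2$p[1, 2]))
})

test_that("selection is detected on synthetic habitat-weighted individuals", {
  cfg <- sim_config(seed = 23, landscape = list(size = 100, cell_size = 50,
                                                proportions = rep(0.2, 5),
                                                patchiness = 3))
  map <- generate_landscape(cfg)
  comps <- lapply(1:7, function(i) {
    ind <- list(species = "fox", animal_id = paste0("F", i),
                centre = c(2500, 2500), sigma = diag(c(700^2, 700^2)),
                weights = c(3, 1, 1, 1, 1), n_locations = 80)
    loc <- generate_individual(ind, map, seed = 400 + i)
    u <- estimate_ud(loc, cell_size = 50)
    composition_type3(loc, isopleth(u, 0.95), map)
  })
  comps <- lapply(comps, zero_replace)
  res <- wilks_test(comps)
  expect_lt(res$p_parametric, 0.05)
  rm <- ranking_matrix(comps)
  expect_equal(unname(rm$rank[1]), 4)  # the favoured habitat tops the ranking
})
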