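# Compositional analysis of habitat selection.
#
# Each individual contributes a composition: a vector of used habitat
# proportions U_1..U_D and a matching availability vector V_1..V_D.  Use
# relative to availability is measured by log-ratio differences
# d_i = ln(U_i/U_ref) - ln(V_i/V_ref); random use means E[d] = 0.  The
# overall test is a one-sample MANOVA on the (D-1)-vectors d across
# individuals: Wilks' lambda = |residual SSP| / |total SSP|, with
# -N ln(lambda) asymptotically chi-squared on D-1 df, plus an exact
# sign-flip randomization alternative.  Pairwise selection is summarized by
# mean log-ratio differences and paired t tests, ranked per habitat.
#
# Two study designs: second-order ("Type II") compares habitat proportions
# in each individual's home range against availability across the species'
# study area (the convex hull around all individuals' home ranges);
# third-order ("Type III") compares the proportions of radio locations per
# habitat against availability within the individual's own home range.

#' Construct a composition record
#'
#' @param individual label.
#' @param use,avail numeric D-vectors of proportions; each is normalized to
#'   sum to 1.
#' @param habitats character vector of the D habitat names.
#' @param design `"II"` or `"III"`.
#' @return Object of class `composition_record`.
#' @export
composition_record <- function(individual, use, avail, habitats,
                               design = c("II", "III")) {
  design <- match.arg(design)
  stopifnot(length(use) == length(habitats), length(avail) == length(habitats))
  if (any(use < 0) || any(avail < 0)) stop("composition proportions must be >= 0")
  if (sum(use) <= 0 || sum(avail) <= 0) stop("composition sums to zero")
  structure(
    list(individual = as.character(individual),
         use = stats::setNames(use / sum(use), habitats),
         avail = stats::setNames(avail / sum(avail), habitats),
         habitats = habitats, design = design),
    class = "composition_record"
  )
}

#' Second-order (Type II) habitat-selection compositions
#'
#' Use = habitat proportions inside each individual's home range (map cells
#' whose centres fall in the home-range region); availability = habitat
#' proportions inside the species' study area, taken as the convex hull of
#' the cell centres of all individuals' home ranges (identical across
#' individuals).
#'
#' @param home_ranges named list of [isopleth()] home ranges, one per
#'   individual.
#' @param map a [habitat_map()].
#' @param study_area optional two-column matrix of polygon vertices (metres)
#'   overriding the convex-hull default.
#' @return List of [composition_record()]s (design `"II"`), with the study
#'   area polygon attached as attribute `study_area`.
#' @export
composition_type2 <- function(home_ranges, map, study_area = NULL) {
  if (length(home_ranges) < 2) {
    stop("composition_type2: need at least 2 individuals")
  }
  if (is.null(study_area)) {
    ctrs <- do.call(rbind, lapply(home_ranges, hr_cell_centres))
    h <- grDevices::chull(ctrs)
    study_area <- ctrs[h, , drop = FALSE]
  }
  ctr <- cell_centres(map$origin, map$cell_size, dim(map$codes))
  xs <- rep(ctr$x, each = nrow(map$codes))
  ys <- rep(ctr$y, times = ncol(map$codes))
  codes <- as.vector(map$codes)
  in_area <- point_in_polygon(xs, ys, study_area[, 1], study_area[, 2]) &
    !is.na(codes)
  if (!any(in_area)) stop("composition_type2: study area misses the map")
  avail <- tabulate(codes[in_area], nbins = length(map$classes))
  avail <- avail / sum(avail)

  recs <- lapply(names(home_ranges) %||% seq_along(home_ranges), function(id) {
    hr <- home_ranges[[id]]
    inside <- hr_contains(hr, xs, ys) & !is.na(codes)
    if (!any(inside)) {
      stop("composition_type2: home range of ", id, " lies outside the map")
    }
    use <- tabulate(codes[inside], nbins = length(map$classes))
    composition_record(id, use / sum(use), avail, map$classes, "II")
  })
  structure(recs, study_area = study_area)
}

hr_cell_centres <- function(hr) {
  ctr <- cell_centres(hr$origin, hr$cell_size, dim(hr$mask))
  idx <- which(hr$mask, arr.ind = TRUE)
  cbind(ctr$x[idx[, 2]], ctr$y[idx[, 1]])
}

#' Third-order (Type III) habitat-selection composition
#'
#' Use = fraction of the individual's radio locations in each habitat class
#' (classes looked up on the map; locations outside the map are rejected
#' with a warning); availability = habitat proportions within the
#' individual's home range.
#'
#' @param points the individual's [location_set()].
#' @param hr the individual's [isopleth()] home range.
#' @param map a [habitat_map()].
#' @param min_locations minimum usable locations (default 20).
#' @return A [composition_record()] (design `"III"`).
#' @export
composition_type3 <- function(points, hr, map, min_locations = 20) {
  xy <- as_xy(points)
  cls <- habitat_at(map, xy[, 1], xy[, 2])
  bad <- is.na(cls)
  if (any(bad)) {
    warning("composition_type3: rejected ", sum(bad),
            " location(s) outside the map for ", points$animal_id)
  }
  cls <- cls[!bad]
  if (length(cls) < min_locations) {
    stop("composition_type3: ", length(cls), " usable locations is below ",
         min_locations)
  }
  use <- tabulate(match(cls, map$classes), nbins = length(map$classes))

  ctr <- cell_centres(map$origin, map$cell_size, dim(map$codes))
  xs <- rep(ctr$x, each = nrow(map$codes))
  ys <- rep(ctr$y, times = ncol(map$codes))
  codes <- as.vector(map$codes)
  inside <- hr_contains(hr, xs, ys) & !is.na(codes)
  if (!any(inside)) stop("composition_type3: home range lies outside the map")
  avail <- tabulate(codes[inside], nbins = length(map$classes))
  composition_record(points$animal_id, use / sum(use), avail / sum(avail),
                     map$classes, "III")
}

#' Replace zero proportions in a composition
#'
#' Substitutes a small positive value for unused habitats so log-ratios are
#' defined, then renormalizes.  The conventional replacement value is 0.01%
#' (0.0001); the substitution can inflate type-I error and is therefore not
#' applied automatically.
#'
#' @param comp a [composition_record()].
#' @param value replacement proportion (default 1e-4).
#' @return The record with zero entries in `use` and `avail` replaced; a
#'   no-op when there are no zeros.
#' @export
zero_replace <- function(comp, value = 1e-4) {
  if (value <= 0) stop("zero_replace: value must be positive")
  fix <- function(p) {
    if (!any(p == 0)) return(p)
    p[p == 0] <- value
    p / sum(p)
  }
  comp$use <- fix(comp$use)
  comp$avail <- fix(comp$avail)
  comp
}

# (D-1) log-ratio difference vectors, one row per individual.
logratio_matrix <- function(comps, reference) {
  habitats <- comps[[1]]$habitats
  if (is.null(reference)) reference <- habitats[length(habitats)]
  if (!reference %in% habitats) stop("unknown reference habitat: ", reference)
  others <- setdiff(habitats, reference)
  y <- t(vapply(comps, function(cm) {
    if (any(cm$use == 0) || any(cm$avail == 0)) {
      stop("composition for ", cm$individual,
           " has zero proportions; apply zero_replace() first")
    }
    log(cm$use[others] / cm$use[reference]) -
      log(cm$avail[others] / cm$avail[reference])
  }, numeric(length(others))))
  colnames(y) <- others
  rownames(y) <- vapply(comps, `[[`, character(1), "individual")
  y
}

wilks_lambda <- function(y) {
  n <- nrow(y)
  ybar <- colMeans(y)
  resid <- sweep(y, 2, ybar)
  ssp_resid <- crossprod(resid)
  ssp_total <- crossprod(y)
  dt <- det(ssp_total)
  if (!is.finite(dt) || dt <= 0) {
    stop("wilks_test: singular total SSP matrix; merge habitat classes or ",
         "use the randomization mode")
  }
  max(.Machine$double.eps, min(1, det(ssp_resid) / dt))
}

#' Overall test of non-random habitat use (Wilks' lambda)
#'
#' One-sample MANOVA on the individuals' log-ratio difference vectors.
#' Lambda in (0, 1]; smaller values mean stronger departure from random use.
#' The parametric p-value compares chi2 = -N ln(lambda) to a chi-squared
#' distribution on D-1 df.  The randomization mode reflects each
#' individual's vector about zero (all 2^N sign patterns when N <= 10, else
#' `n_resamples` random patterns) and reports the fraction of resampled
#' lambdas at or below the observed one.
#'
#' @param comps list of [composition_record()]s with a common habitat set
#'   and design.
#' @param reference reference habitat for the log-ratios (default: last
#'   class; lambda and the p-values do not depend on this choice).
#' @param mode `"parametric"`, `"randomization"`, or `"both"`.
#' @param n_resamples randomization resamples when N > 10 (default 999).
#' @param seed optional seed for the randomization draw.
#' @return Object of class `selection_test`: `lambda`, `chi2`, `df`,
#'   `p_parametric`, `p_randomization` (NA unless requested), `n`, `design`.
#' @export
wilks_test <- function(comps, reference = NULL,
                       mode = c("parametric", "randomization", "both"),
                       n_resamples = 999, seed = NULL) {
  mode <- match.arg(mode)
  y <- logratio_matrix(comps, reference)
  n <- nrow(y); d <- ncol(y)
  if (mode %in% c("parametric", "both") && n < d + 1) {
    stop("wilks_test: parametric mode needs at least D individuals (N >= ",
         d + 1, "), got ", n)
  }
  lambda <- wilks_lambda(y)
  chi2 <- -n * log(lambda)
  p_par <- stats::pchisq(chi2, df = d, lower.tail = FALSE)

  p_rand <- NA_real_
  if (mode %in% c("randomization", "both")) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    }
    if (n <= 10) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      lam <- apply(signs, 1, function(s) wilks_lambda(y * s))
      p_rand <- mean(lam <= lambda + 1e-12)
    } else {
      lam <- replicate(n_resamples, {
        wilks_lambda(y * sample(c(-1, 1), n, replace = TRUE))
      })
      p_rand <- (1 + sum(lam <= lambda + 1e-12)) / (1 + n_resamples)
    }
  }
  structure(
    list(lambda = lambda, chi2 = chi2, df = d, p_parametric = p_par,
         p_randomization = p_rand, n = n, design = comps[[1]]$design),
    class = "selection_test"
  )
}

#' @export
print.selection_test <- function(x, ...) {
  cat(sprintf(
    "<selection_test> design %s, N = %d: lambda = %.3f, chi2(%d) = %.3f, p = %.3f",
    x$design, x$n, x$lambda, x$df, x$chi2, x$p_parametric))
  if (!is.na(x$p_randomization)) {
    cat(sprintf(" (randomization p = %.3f)", x$p_randomization))
  }
  cat("\n")
  invisible(x)
}

#' Pairwise habitat ranking matrix
#'
#' For every habitat pair (i, j), the mean over individuals of
#' d_ij = ln(U_i/U_j) - ln(V_i/V_j), a paired one-sample t statistic and
#' its two-sided p-value.  Habitat i's rank is the number of habitats it
#' dominates (mean_diff > 0); D-1 marks the most-selected habitat.
#'
#' @param comps list of [composition_record()]s.
#' @return Object of class `ranking_matrix`: `habitats`, `mean_diff`
#'   (antisymmetric D x D), `stat` (paired t), `p` (two-sided; NA on the
#'   diagonal, marked degenerate — `NaN` — for zero-variance pairs), `rank`
#'   (named integer vector, 0..D-1).
#' @export
ranking_matrix <- function(comps) {
  if (length(comps) < 2) stop("ranking_matrix: need at least 2 individuals")
  habitats <- comps[[1]]$habitats
  d <- length(habitats)
  u <- t(vapply(comps, `[[`, numeric(d), "use"))
  v <- t(vapply(comps, `[[`, numeric(d), "avail"))
  if (any(u == 0) || any(v == 0)) {
    stop("ranking_matrix: zero proportions; apply zero_replace() first")
  }
  lr <- log(u) - log(v)  # d_ij = lr[, i] - lr[, j] per individual
  mean_diff <- stat <- p <- matrix(NA_real_, d, d,
                                   dimnames = list(habitats, habitats))
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (i == j) next
    dij <- lr[, i] - lr[, j]
    mean_diff[i, j] <- mean(dij)
    if (stats::sd(dij) == 0) {
      stat[i, j] <- if (mean(dij) == 0) 0 else sign(mean(dij)) * Inf
      p[i, j] <- NaN  # degenerate: no variance across individuals
    } else {
      tt <- stats::t.test(dij)
      stat[i, j] <- unname(tt$statistic)
      p[i, j] <- tt$p.value
    }
  }
  rank <- apply(mean_diff > 0, 1, sum, na.rm = TRUE)
  structure(list(habitats = habitats, mean_diff = mean_diff, stat = stat,
                 p = p, rank = rank),
            class = "ranking_matrix")
}

#' @export
print.ranking_matrix <- function(x, ...) {
  d <- length(x$habitats)
  disp <- matrix(".", d, d, dimnames = list(x$habitats, x$habitats))
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (i != j) disp[i, j] <- sprintf("%.3f (%.2f)", x$stat[i, j], x$p[i, j])
  }
  cat("<ranking_matrix> paired t (p two-sided); rank = habitats dominated\n")
  print(cbind(disp, Ranking = x$rank), quote = FALSE)
  invisible(x)
}

#' Write a ranking matrix as CSV
#'
#' Upper-triangle pairwise t statistics with p-values in parentheses and a
#' Ranking column, mirroring the conventional compositional-analysis table.
#'
#' @param x a `ranking_matrix`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_ranking_csv <- function(x, path) {
  d <- length(x$habitats)
  m <- matrix("", d, d, dimnames = list(x$habitats, x$habitats))
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (i != j) m[i, j] <- sprintf("%.3f (%.2f)", x$stat[i, j], x$p[i, j])
  }
  df <- data.frame(habitat = x$habitats, m, Ranking = x$rank,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
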