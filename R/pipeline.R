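# One-call orchestration: simulate (or load) inputs, then run home ranges,
# overlap, habitat selection and activity analysis, writing
# publication-style CSV tables to an output directory.  All randomness is
# routed through a single master seed so reruns are byte-identical.

#' Read a pipeline run configuration from YAML
#'
#' Flat keys: `seed`, `out_dir`, `isopleth_level`, `cell_size`,
#' `min_locations`, `design` ("II", "III" or "both"), `zero_replace`
#' (logical), `zero_value`, `kappa` (optional fixed activity kappa),
#' `latitude`, `longitude`, `utc_offset`, and either `simulate: true` with a
#' nested `simulation` block (passed to [sim_config()]) or input paths
#' `locations_csv`, `habitat_asc`, `habitat_legend`, `camera_csv`.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(validate_run_config(cfg), class = "run_config")
}

validate_run_config <- function(cfg) {
  cfg <- utils::modifyList(list(
    seed = 1L, isopleth_level = 0.95, cell_size = 50, min_locations = 20,
    design = "both", zero_replace = FALSE, zero_value = 1e-4,
    kappa = NULL, latitude = -18.98, longitude = -56.65, utc_offset = -4,
    simulate = FALSE
  ), cfg)
  if (cfg$isopleth_level <= 0 || cfg$isopleth_level > 1) {
    stop("run config: isopleth_level must be in (0, 1]")
  }
  if (!isTRUE(cfg$simulate)) {
    for (key in c("locations_csv", "habitat_asc", "habitat_legend")) {
      if (is.null(cfg[[key]])) {
        stop("run config: missing input '", key,
             "' (required unless simulate: true)")
      }
      if (!file.exists(cfg[[key]])) {
        stop("run config: input file not found: ", cfg[[key]])
      }
    }
  }
  cfg
}

#' Run the full niche-partitioning pipeline
#'
#' Stages: (1) simulate or load the habitat map, telemetry and camera
#' records; (2) per-individual UDs, 95% home ranges, MCP accumulation
#' curves and a per-species summary table; (3) species-level PHR/UDOI
#' overlap matrix; (4) compositional habitat selection at the requested
#' design(s); (5) sun-adjusted activity densities, isopleths and the
#' pairwise overlap matrix.  Each stage logs one line; any stage error
#' aborts with the stage name.
#'
#' @param cfg a `run_config` list (see [read_run_config()]) or path to one.
#' @param out_dir output directory (overrides `cfg$out_dir`).
#' @return Invisibly, a list with the per-stage results (`map`,
#'   `locations`, `uds`, `home_ranges`, `hr_table`, `overlap`, `selection`,
#'   `activity`, `camera_table`).
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(unclass(cfg))
  out_dir <- out_dir %||% cfg$out_dir %||% stop("run_pipeline: no out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, ...) {
    line <- paste0("[", stage, "] ", paste0(..., collapse = ""))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  cat("# nichekit ", as.character(utils::packageVersion("nichekit")),
      " seed=", cfg$seed, " ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), "\n",
      file = log_path, sep = "")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- inputs -----------------------------------------------------------
  inputs <- stage("inputs", {
    if (isTRUE(cfg$simulate)) {
      sim <- simulate_study(do.call(sim_config, c(list(seed = cfg$seed),
                                                  cfg$simulation %||% list())))
      write_habitat_map(sim$map, file.path(out_dir, "habitat.asc"),
                        file.path(out_dir, "habitat_legend.csv"))
      write_locations_csv(sim$locations, file.path(out_dir, "telemetry.csv"))
      cam <- sim$camera
      cam_out <- cam
      cam_out$datetime <- format(cam_out$datetime, "%Y-%m-%dT%H:%M:%S")
      utils::write.csv(cam_out, file.path(out_dir, "camera.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        sim_truth_json(sim), file.path(out_dir, "truth.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      list(map = sim$map, locations = sim$locations, camera = cam,
           trap_days = attr(cam, "trap_days"))
    } else {
      cam <- if (!is.null(cfg$camera_csv)) read_camera_records(cfg$camera_csv)
      list(map = read_habitat_map(cfg$habitat_asc, cfg$habitat_legend),
           locations = read_locations(cfg$locations_csv),
           camera = cam, trap_days = cfg$trap_days)
    }
  })
  logf("inputs", length(inputs$locations), " animals, ",
       if (is.null(inputs$camera)) 0 else nrow(inputs$camera),
       " camera records, map ", nrow(inputs$map$codes), "x",
       ncol(inputs$map$codes))

  # -- home ranges ------------------------------------------------------
  hr_res <- stage("homerange", {
    usable <- Filter(function(l) nrow(l$points) >= cfg$min_locations,
                     inputs$locations)
    if (length(usable) < length(inputs$locations)) {
      logf("homerange", "excluded ",
           length(inputs$locations) - length(usable),
           " animal(s) under the ", cfg$min_locations, "-location rule")
    }
    uds <- lapply(usable, estimate_ud, cell_size = cfg$cell_size,
                  min_locations = cfg$min_locations)
    hrs <- lapply(uds, isopleth, level = cfg$isopleth_level)
    tab <- data.frame(
      animal_id = vapply(usable, `[[`, character(1), "animal_id"),
      species = vapply(usable, `[[`, character(1), "species"),
      n_locations = vapply(usable, function(l) nrow(l$points), integer(1)),
      ud_km2 = round(vapply(hrs, `[[`, numeric(1), "area_km2"), 1),
      mcp_km2 = round(vapply(usable, function(l) mcp(l)$area_km2, numeric(1)), 1),
      row.names = NULL
    )
    utils::write.csv(tab, file.path(out_dir, "home_ranges.csv"),
                     row.names = FALSE)
    summ <- summarize_home_ranges(
      vapply(hrs, `[[`, numeric(1), "area_km2"), tab$species)
    utils::write.csv(summ, file.path(out_dir, "home_range_summary.csv"),
                     row.names = FALSE)
    acc <- do.call(rbind, lapply(usable, function(l) {
      cbind(animal_id = l$animal_id, accumulation_curve(l))
    }))
    utils::write.csv(acc, file.path(out_dir, "accumulation_curves.csv"),
                     row.names = FALSE)
    for (id in names(uds)) {
      write_ud_grid(uds[[id]], file.path(out_dir, paste0("ud_", id, ".asc")))
    }
    list(locations = usable, uds = uds, hrs = hrs, table = tab, summary = summ)
  })
  logf("homerange", nrow(hr_res$table), " UDs at level ", cfg$isopleth_level)

  # -- overlap ----------------------------------------------------------
  ovl <- stage("overlap", {
    o <- species_overlap_matrix(hr_res$locations, level = cfg$isopleth_level,
                                cell_size = cfg$cell_size,
                                min_locations = cfg$min_locations)
    write_overlap_csv(o, file.path(out_dir, "overlap.csv"))
    o
  })
  logf("overlap", length(ovl$labels), " species matrix written")

  # -- habitat selection ------------------------------------------------
  sel <- stage("habitat_selection", {
    designs <- if (cfg$design == "both") c("II", "III") else cfg$design
    res <- list()
    species <- unique(vapply(hr_res$locations, `[[`, character(1), "species"))
    for (sp in species) {
      ids <- names(Filter(function(l) l$species == sp, hr_res$locations))
      if (length(ids) < 2) next
      for (dsn in designs) {
        comps <- if (dsn == "II") {
          composition_type2(hr_res$hrs[ids], inputs$map)
        } else {
          lapply(ids, function(id) {
            composition_type3(hr_res$locations[[id]], hr_res$hrs[[id]],
                              inputs$map, min_locations = cfg$min_locations)
          })
        }
        if (isTRUE(cfg$zero_replace)) {
          comps <- lapply(comps, zero_replace, value = cfg$zero_value)
        }
        key <- paste0(sp, "_type", dsn)
        res[[key]] <- tryCatch(
          list(test = wilks_test(comps, mode = "both", seed = cfg$seed),
               ranking = ranking_matrix(comps)),
          error = function(e) {
            logf("habitat_selection", key, " skipped: ", conditionMessage(e))
            NULL
          })
        if (!is.null(res[[key]])) {
          write_ranking_csv(res[[key]]$ranking,
                            file.path(out_dir, paste0("ranking_", key, ".csv")))
        }
      }
    }
    tests <- Filter(Negate(is.null), res)
    if (length(tests)) {
      tab <- do.call(rbind, lapply(names(tests), function(k) {
        tt <- tests[[k]]$test
        data.frame(analysis = k, design = tt$design, n = tt$n,
                   lambda = tt$lambda, chi2 = tt$chi2, df = tt$df,
                   p_parametric = tt$p_parametric,
                   p_randomization = tt$p_randomization)
      }))
      utils::write.csv(tab, file.path(out_dir, "selection_tests.csv"),
                       row.names = FALSE)
    }
    res
  })
  logf("habitat_selection", length(sel), " analyses")

  # -- activity ---------------------------------------------------------
  act <- stage("activity", {
    if (is.null(inputs$camera) || nrow(inputs$camera) == 0) {
      logf("activity", "no camera records; stage skipped")
      NULL
    } else {
      rec <- sun_adjust_records(inputs$camera, cfg$latitude, cfg$longitude,
                                cfg$utc_offset)
      ovm <- activity_overlap_matrix(rec, level = cfg$isopleth_level,
                                     kappa = cfg$kappa)
      utils::write.csv(as.data.frame(ovm$overlap),
                       file.path(out_dir, "activity_overlap.csv"))
      dens <- do.call(cbind, lapply(ovm$densities, `[[`, "density"))
      utils::write.csv(
        data.frame(sun_hour = ovm$densities[[1]]$hours, dens),
        file.path(out_dir, "activity_density.csv"), row.names = FALSE)
      cam_tab <- camera_summary(inputs$camera, trap_days = inputs$trap_days)
      utils::write.csv(cam_tab, file.path(out_dir, "camera_summary.csv"),
                       row.names = FALSE)
      list(overlap = ovm, camera_table = cam_tab)
    }
  })
  if (!is.null(act)) {
    logf("activity", ncol(act$overlap$overlap), " species overlap matrix")
  }

  invisible(list(map = inputs$map, locations = hr_res$locations,
                 uds = hr_res$uds, home_ranges = hr_res$hrs,
                 hr_table = hr_res$table, hr_summary = hr_res$summary,
                 overlap = ovl, selection = sel, activity = act))
}

#' Write location sets to a telemetry CSV
#'
#' @param locations list of [location_set()]s.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_locations_csv <- function(locations, path) {
  df <- do.call(rbind, lapply(locations, function(l) {
    d <- data.frame(animal_id = l$animal_id, species = l$species,
                    x = l$points$x, y = l$points$y,
                    timestamp = format(l$points$t, "%Y-%m-%dT%H:%M:%S"),
                    stringsAsFactors = FALSE)
    if (!is.null(l$points$habitat)) d$habitat <- l$points$habitat
    if (!is.null(l$points$active)) d$active <- l$points$active
    d
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

sim_truth_json <- function(sim) {
  lapply(sim$truth, function(tr) {
    if (is.list(tr) && !is.null(tr$sigma)) {
      tr$sigma <- as.vector(tr$sigma)
    }
    tr
  })
}
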