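#' Run the full analysis pipeline from a configuration file
#'
#' Executes the requested stages in workflow order — simulate (or load)
#' sheet images, detect zones, quantify, calibrate, radial profiling, heat
#' maps, stack growth, migration — writing each stage's outputs under
#' `out_dir` and recording a run manifest (config snapshot, seed, file
#' digests, per-stage outputs). Stages only read artifacts written by earlier
#' stages, so a partial failure leaves completed outputs intact, and a stage
#' whose input artifact is missing fails naming it.
#'
#' The top-level `seed` is fanned out deterministically to per-layer
#' simulation seeds, so identical config + seed reproduce identical outputs.
#'
#' @param config_path path to the YAML/JSON configuration.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the stochastic stages.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "detect", "quantify", "calibrate", "radial", "heatmap",
#'   "stack-growth", "migrate")`; default from the config (`stages:` key) or
#'   all applicable.
#' @param verbose print a timestamped line per stage.
#' @return The run manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config_path, out_dir, seed = 1L, stages = NULL,
                         verbose = TRUE) {
  cfg <- load_config(config_path)
  raw <- cfg$raw
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("simulate", "detect", "quantify", "calibrate", "radial",
                  "heatmap", "stack-growth", "migrate")
  stages <- stages %||% unlist(raw$stages) %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  say <- function(...) if (verbose)
    message(format(Sys.time(), "%H:%M:%S "), "[zonestack] ", ...)
  p_img <- function(l) file.path(out_dir, sprintf("image_%s.tif", l))
  p_truth <- function(l) file.path(out_dir, sprintf("truth_%s.csv", l))
  p_fits <- function(l) file.path(out_dir, sprintf("fits_%s.csv", l))
  need <- function(path, stage) {
    if (!file.exists(path))
      stop("missing artifact: ", basename(path),
           " (run stage '", stage, "' first)")
    path
  }
  manifest <- list(tool = "zonestack",
                   version = as.character(utils::packageVersion("zonestack")),
                   seed = seed, config = raw,
                   config_digest = unname(tools::md5sum(config_path)),
                   stages = list())
  done <- function(stage, outputs) {
    manifest$stages[[stage]] <<- list(
      outputs = outputs,
      digests = as.list(tools::md5sum(unlist(outputs))))
  }

  sim_cfg <- raw$simulate %||% list()
  layer_ids <- unlist(sim_cfg$layers) %||%
    (if (length(cfg$stacks)) cfg$stacks[[1]]$layers else "L1")
  conditions <- sim_cfg$conditions %||% list(H = 120000, L = 12000, empty = 0)

  if ("simulate" %in% stages) {
    say("simulate: ", length(layer_ids), " layer(s)")
    sp <- sim_cfg$params %||% list()
    for (i in seq_along(layer_ids)) {
      l <- layer_ids[i]
      params <- sheet_sim_params(
        n_rows = cfg$grid$n_rows, n_cols = cfg$grid$n_cols,
        pitch_um = cfg$grid$pitch_um,
        zone_radius_um = cfg$grid$zone_radius_um, pixel_um = cfg$pixel_um,
        rim_fraction = sp$rim_fraction %||% 0.15,
        warp_amplitude_px = sp$warp_amplitude_px %||% 3,
        warp_scale_px = sp$warp_scale_px %||% 200,
        noise_sd = sp$noise_sd %||% 0,
        seed = (seed * 131L + i) %% .Machine$integer.max)
      # per-layer seeding: stack designs override the plate-map condition
      cond <- cfg$plate_map$condition
      for (s in cfg$stacks) {
        lay <- s$seeding[s$seeding$layer_id == l, ]
        if (nrow(lay))
          cond[cfg$plate_map$experiment == s$stack_id] <- lay$condition[1]
      }
      cells <- vapply(cond, function(cn)
        as.numeric(conditions[[cn]] %||% 0), numeric(1))
      zv <- data.frame(row = cfg$plate_map$row, col = cfg$plate_map$col,
                       cells = cells)
      sim <- generate_sheet(params, zv, layer_id = l)
      write_sheet(sim$image, p_img(l))
      write_ground_truth(sim, p_truth(l))
    }
    outs <- c(lapply(layer_ids, p_img), lapply(layer_ids, p_truth))
    if (!is.null(raw$calibration)) {
      # dedicated calibration sheet: one concentration per grid row
      cal_cells <- as.numeric(unlist(raw$calibration$cells))
      params <- sheet_sim_params(
        n_rows = cfg$grid$n_rows, n_cols = cfg$grid$n_cols,
        pitch_um = cfg$grid$pitch_um,
        zone_radius_um = cfg$grid$zone_radius_um, pixel_um = cfg$pixel_um,
        rim_fraction = sp$rim_fraction %||% 0.15,
        warp_amplitude_px = sp$warp_amplitude_px %||% 3,
        warp_scale_px = sp$warp_scale_px %||% 200,
        noise_sd = sp$noise_sd %||% 0,
        seed = (seed * 131L + length(layer_ids) + 1L) %% .Machine$integer.max)
      zv <- matrix(rep_len(cal_cells, cfg$grid$n_rows), cfg$grid$n_rows,
                   cfg$grid$n_cols)
      sim <- generate_sheet(params, zv, layer_id = "CAL")
      write_sheet(sim$image, p_img("CAL"))
      write_ground_truth(sim, p_truth("CAL"))
      outs <- c(outs, p_img("CAL"), p_truth("CAL"))
    }
    done("simulate", outs)
  }

  if ("detect" %in% stages) {
    say("detect: fitting zone circles")
    for (l in layer_ids) {
      img <- read_sheet(need(p_img(l), "simulate"), cfg$pixel_um,
                        layer_id = l)
      fits <- detect_zones(img, cfg$grid)
      utils::write.csv(fits, p_fits(l), row.names = FALSE)
    }
    done("detect", lapply(layer_ids, p_fits))
  }

  zones_path <- file.path(out_dir, "zones.csv")
  if ("quantify" %in% stages) {
    say("quantify: zone intensities")
    tabs <- lapply(layer_ids, function(l) {
      img <- read_sheet(need(p_img(l), "simulate"), cfg$pixel_um,
                        layer_id = l)
      fits <- utils::read.csv(need(p_fits(l), "detect"))
      mz <- measure_zones(img, fits, bg_factor = cfg$quantify$bg_factor)
      results_table(mz, cfg$plate_map)
    })
    export_results(do.call(rbind, tabs), zones_path, "csv")
    done("quantify", list(zones_path))
  }

  curve_path <- file.path(out_dir, "curve.json")
  if ("calibrate" %in% stages) {
    say("calibrate: intensity -> cells")
    if (!is.null(raw$calibration)) {
      img <- read_sheet(need(p_img("CAL"), "simulate"), cfg$pixel_um,
                        layer_id = "CAL")
      fits <- detect_zones(img, cfg$grid)
      mz <- measure_zones(img, fits, bg_factor = cfg$quantify$bg_factor)
      truth <- utils::read.csv(need(p_truth("CAL"), "simulate"))
      m <- merge(mz, truth, by = c("row", "col"))
    } else {
      zones <- import_results(need(zones_path, "quantify"))
      zones <- zones[zones$ring == "zone-mean", ]
      truth <- do.call(rbind, lapply(layer_ids, function(l) {
        tr <- utils::read.csv(need(p_truth(l), "simulate"))
        tr$layer <- l; tr
      }))
      m <- merge(zones, truth, by = c("layer", "row", "col"))
    }
    curve <- fit_calibration(cells = m$cells, corrected = m$corrected)
    jsonlite::write_json(list(form = curve$form,
                              coefficients = as.list(curve$coefficients),
                              cells_range = curve$cells_range,
                              intensity_range = curve$intensity_range),
                         curve_path, auto_unbox = TRUE, digits = NA)
    done("calibrate", list(curve_path))
  }

  profiles_path <- file.path(out_dir, "profiles.csv")
  if ("radial" %in% stages) {
    say("radial: half-radial profiles")
    profs <- list()
    for (l in layer_ids) {
      img <- read_sheet(need(p_img(l), "simulate"), cfg$pixel_um,
                        layer_id = l)
      fits <- utils::read.csv(need(p_fits(l), "detect"))
      ok <- fits[fits$provenance != "failed", ]
      profs <- c(profs, lapply(seq_len(nrow(ok)), function(i)
        half_radial_profile(img, ok[i, ],
                            outer_factor = cfg$quantify$outer_factor)))
    }
    utils::write.csv(profiles_table(profs), profiles_path, row.names = FALSE)
    done("radial", list(profiles_path))
  }

  heatmap_path <- file.path(out_dir, "heatmap.png")
  if ("heatmap" %in% stages) {
    say("heatmap: assembling replicate/layer map")
    pt <- utils::read.csv(need(profiles_path, "radial"))
    profs <- lapply(split(pt, list(pt$layer, pt$row, pt$col), drop = TRUE),
                    function(d) {
      d <- d[order(d$ring), ]
      structure(list(layer = d$layer[1], channel = d$channel[1],
                     row = d$row[1], col = d$col[1], axis_angle = 0,
                     n_rings = nrow(d), left = d$left, right = d$right,
                     n_left = d$n_left, n_right = d$n_right),
                class = "radial_profile")
    })
    hm <- assemble_heatmap(unname(profs), cfg$plate_map,
                           layer_order = layer_ids)
    render_heatmap(hm, heatmap_path)
    done("heatmap", list(heatmap_path, sub("\\.png$", ".csv", heatmap_path)))
  }

  growth_path <- file.path(out_dir, "growth.csv")
  if ("stack-growth" %in% stages && length(cfg$stacks)) {
    say("stack-growth: per-layer growth statistics")
    zones <- import_results(need(zones_path, "quantify"))
    zones <- zones[zones$ring == "zone-mean", ]
    curve <- if (file.exists(curve_path)) {
      cj <- jsonlite::read_json(curve_path, simplifyVector = TRUE)
      structure(list(form = cj$form, coefficients = unlist(cj$coefficients),
                     cells_range = cj$cells_range,
                     intensity_range = cj$intensity_range),
                class = "calibration_curve")
    } else NULL
    if (!is.null(curve))
      zones$cells_est <- as.numeric(cells_from_intensity(curve, zones$corrected))
    gt <- do.call(rbind, lapply(cfg$stacks, function(s) {
      z <- zones[zones$experiment == s$stack_id | length(cfg$stacks) == 1L, ]
      res <- data.frame(layer_id = z$layer, replicate = z$replicate,
                        cells_est = z$cells_est)
      g <- growth_table(res, s)
      g$stack_id <- s$stack_id
      g
    }))
    utils::write.csv(gt, growth_path, row.names = FALSE)
    done("stack-growth", list(growth_path))
  }

  migration_path <- file.path(out_dir, "migration.csv")
  if ("migrate" %in% stages && !is.null(raw$migrate)) {
    say("migrate: layer-to-layer fractions")
    zones <- import_results(need(zones_path, "quantify"))
    zones <- zones[zones$ring == "zone-mean", ]
    mg <- do.call(rbind, lapply(raw$migrate, function(pr) {
      snd <- zones[zones$layer == pr$sender, ]
      rcv <- zones[zones$layer == pr$receiver, ]
      m <- merge(snd, rcv, by = c("experiment", "replicate", "row", "col"),
                 suffixes = c("_sender", "_receiver"))
      data.frame(sender = pr$sender, receiver = pr$receiver,
                 direction = pr$direction %||% "up",
                 experiment = m$experiment, replicate = m$replicate,
                 fraction = migration_fraction(pmax(m$corrected_sender, 0),
                                               pmax(m$corrected_receiver, 0)))
    }))
    utils::write.csv(mg, migration_path, row.names = FALSE)
    done("migrate", list(migration_path))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  say("done; manifest at ", manifest_path)
  invisible(manifest)
}
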