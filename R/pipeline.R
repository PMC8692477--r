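## End-to-end pipeline runner: reproduces the study's computational
## figures and tables from configuration alone, writing artifacts and a
## run manifest into an output directory.

.write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  path
}

.write_heatmap_png <- function(m, grid, path, title) {
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::image(x = grid$r * 1e3, y = grid$z * 1e3,
                  z = m, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "r (mm)", ylab = "z (mm)", main = title)
  path
}

.compute_error <- function(msg) {
  stop(structure(class = c("espray_compute_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Run the full device-and-assay pipeline
#'
#' Reproduces the computational results of the study from configuration
#' alone: solves the device at the primary and comparison potentials on
#' one grid, writes tip-field reports, profiles, maps and the linearity
#' check; evaluates the force scales, spraying mode, droplet bounds and
#' cell-exposure metrics; and runs the synthetic quantification
#' demonstrations (droplet sizing, spheroid areas, viability, ddCt, DEG
#' filter and GO tally) with planted ground truth. Every artifact is
#' listed in a JSON run manifest with per-stage status and timing.
#'
#' @param config a configuration list, e.g. [espray_default_config()] or
#'   [read_run_config()]
#' @param out_dir output directory (created if needed)
#' @param seed RNG seed for the synthetic stages; defaults to the config
#'   seed
#' @return the run manifest (class `espray_manifest`), invisibly; its
#'   `ok` field is `FALSE` when any stage failed
#' @export
run_paper_pipeline <- function(config = espray_default_config(),
                               out_dir = tempfile("espray-run-"),
                               seed = config$seed) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "espray",
                   version = as.character(utils::packageVersion("espray")),
                   seed = as.integer(seed), config = config,
                   out_dir = normalizePath(out_dir), stages = list(),
                   files = character(0), ok = TRUE)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      list(status = "ok", outputs = fn(), message = NULL),
      error = function(e)
        list(status = "error", outputs = character(0),
             message = conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      status = res$status, seconds = round(proc.time()[["elapsed"]] - t0, 3),
      message = res$message, outputs = as.character(res$outputs))
    if (res$status == "error") manifest$ok <<- FALSE
    manifest$files <<- c(manifest$files, as.character(res$outputs))
    invisible(res$status == "ok")
  }
  path <- function(...) file.path(out_dir, paste0(...))

  run_stage("field_solve", function() {
    geom <- .config_geometry(config)
    grid_a <- build_grid(geom, .config_potential(config),
                         spacing = config$spacing_um * 1e-6,
                         mode = config$mode,
                         outer_boundary = config$outer_boundary)
    grid_b <- build_grid(geom,
                         .config_potential(config,
                                           config$comparison_potential_kv),
                         spacing = config$spacing_um * 1e-6,
                         mode = config$mode,
                         outer_boundary = config$outer_boundary)
    fa <- compute_field(solve_poisson(grid_a))
    fb <- compute_field(solve_poisson(grid_b))
    state$field_a <- fa
    ra <- tip_field_report(fa); rb <- tip_field_report(fb)
    state$report_a <- ra
    files <- character(0)
    for (x in list(list(f = fa, r = ra, tag = sprintf("%gkV", config$potential_kv)),
                   list(f = fb, r = rb,
                        tag = sprintf("%gkV", config$comparison_potential_kv)))) {
      tag <- x$tag
      files <- c(files,
        .write_matrix_csv(x$f$grid$mask, path("conductor_mask.csv")),
        .write_matrix_csv(x$f$magnitude, path("field_magnitude_", tag, ".csv")),
        .write_heatmap_png(x$f$magnitude, x$f$grid,
                           path("field_magnitude_", tag, ".png"),
                           sprintf("|E| (V/m) at %s", tag)))
      ap <- axial_profile(x$f); tp <- transverse_tip_profile(x$f)
      write.csv(data.frame(position_m = ap$position,
                           E_V_per_m = ap$magnitude),
                path("axial_profile_", tag, ".csv"), row.names = FALSE)
      write.csv(data.frame(position_m = tp$position,
                           E_V_per_m = tp$magnitude),
                path("transverse_profile_", tag, ".csv"), row.names = FALSE)
      rep_flat <- x$r[setdiff(names(x$r), "grid")]
      jsonlite::write_json(rep_flat, path("tip_report_", tag, ".json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, path("axial_profile_", tag, ".csv"),
                 path("transverse_profile_", tag, ".csv"),
                 path("tip_report_", tag, ".json"))
    }
    lin <- scale_linearity_check(ra, rb)
    write.csv(lin, path("linearity_check.csv"), row.names = FALSE)
    if (!all(lin$ok))
      .compute_error("field linearity check failed on the shared grid")
    c(files, path("linearity_check.csv"))
  })

  run_stage("ehd_report", function() {
    fluid <- .config_fluid(config)
    geom <- .config_geometry(config)
    files <- character(0)
    for (kv in c(config$potential_kv, config$comparison_potential_kv)) {
      op <- operating_conditions(applied_potential = kv * 1e3,
                                 flow_ul_min = config$flow_ul_min,
                                 geometry = geom)
      fs <- force_scales(fluid, op)
      mode <- classify_mode(fs)
      rec <- list(potential_kv = kv,
                  f_electric_N = fs$f_electric, f_gravity_N = fs$f_gravity,
                  p_inertial_N = fs$p_inertial,
                  f_surface_tension_N = fs$f_surface_tension,
                  electric_to_surface_tension = mode$ratio,
                  mode = mode$mode,
                  droplet_diameter_bounds_um =
                    droplet_diameter_bounds(geom) * 1e6)
      f <- path(sprintf("ehd_report_%gkV.json", kv))
      jsonlite::write_json(rec, f, auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
    }
    if (!is.null(state$field_a)) {
      op <- operating_conditions(applied_potential = config$potential_kv * 1e3,
                                 flow_ul_min = config$flow_ul_min,
                                 geometry = geom)
      ex <- exposure_report(op, state$field_a)
      f <- path(sprintf("exposure_%gkV.json", config$potential_kv))
      jsonlite::write_json(ex[c("mean_exit_velocity",
                                "needle_residence_time",
                                "peak_field_on_path",
                                "field_at_exit_center")],
                           f, auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
    }
    files
  })

  run_stage("droplet_quant", function() {
    gen <- synth_droplet_frames(n_frames = 3, seed = seed)
    det <- do.call(rbind, lapply(seq_along(gen$frames), function(i)
      detect_droplets(gen$frames[[i]], frame_index = i)))
    stats <- droplet_diameter_stats(det)
    write.csv(gen$truth, path("droplet_truth.csv"), row.names = FALSE)
    write.csv(det, path("droplet_detections.csv"), row.names = FALSE)
    write.csv(stats, path("droplet_stats.csv"), row.names = FALSE)
    write_frame(gen$frames[[1]], path("droplet_frame1.png"))
    c(path("droplet_truth.csv"), path("droplet_detections.csv"),
      path("droplet_stats.csv"), path("droplet_frame1.png"))
  })

  run_stage("spheroid_quant", function() {
    study <- synth_spheroid_study(seed = seed + 1)
    idx <- study$images$index
    recs <- do.call(rbind, lapply(seq_len(nrow(idx)), function(i) {
      r <- segment_spheroids(study$images$frames[[i]])
      if (!nrow(r)) return(NULL)
      r$dish <- idx$dish[i]; r$day <- idx$day[i]; r$image <- i
      r
    }))
    summ <- spheroid_area_summary(recs)
    write.csv(study$truth, path("spheroid_truth.csv"), row.names = FALSE)
    write.csv(recs, path("spheroid_records.csv"), row.names = FALSE)
    write.csv(summ$per_dish, path("spheroid_per_dish.csv"), row.names = FALSE)
    write.csv(summ$per_day, path("spheroid_per_day.csv"), row.names = FALSE)
    c(path("spheroid_truth.csv"), path("spheroid_records.csv"),
      path("spheroid_per_dish.csv"), path("spheroid_per_day.csv"))
  })

  run_stage("assay_stats", function() {
    od <- synth_od_table(seed = seed + 2)
    ctrl <- od$od[od$group == "control"]
    viab <- do.call(rbind, lapply(setdiff(unique(od$group), "control"),
      function(g) data.frame(group = g,
                             viability_pct = viability_percent(
                               od$od[od$group == g], ctrl))))
    ct <- synth_ct_table(seed = seed + 3)
    dd <- do.call(rbind, lapply(names(attr(ct, "truth")), function(g)
      delta_delta_ct(ct, g, "treated", "control")))
    deg <- synth_deg_table(seed = seed + 4)
    flt <- deg_filter(deg)
    go <- go_term_summary(deg, attr(deg, "go_terms")[[1]],
                          term_name = names(attr(deg, "go_terms"))[1])
    write.csv(od, path("od_table.csv"), row.names = FALSE)
    write.csv(viab, path("viability.csv"), row.names = FALSE)
    write.csv(ct, path("ct_table.csv"), row.names = FALSE)
    write.csv(dd, path("ddct.csv"), row.names = FALSE)
    write.csv(deg, path("deg_table.csv"), row.names = FALSE)
    jsonlite::write_json(list(upregulated = flt$upregulated,
                              downregulated = flt$downregulated),
                         path("deg_filter.json"))
    write.csv(go, path("go_summary.csv"), row.names = FALSE)
    c(path("od_table.csv"), path("viability.csv"), path("ct_table.csv"),
      path("ddct.csv"), path("deg_table.csv"), path("deg_filter.json"),
      path("go_summary.csv"))
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  class(manifest) <- "espray_manifest"
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' @export
print.espray_manifest <- function(x, ...) {
  cat(sprintf("<espray run manifest> v%s, seed %d, %s\n", x$version, x$seed,
              if (x$ok) "all stages ok" else "STAGE FAILURES"))
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-15s %-6s %7.2fs  %d file(s)%s\n", nm, s$status,
                s$seconds, length(s$outputs),
                if (!is.null(s$message)) paste0("  [", s$message, "]") else ""))
  }
  cat(sprintf("  output: %s\n", x$out_dir))
  invisible(x)
}
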