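#' Default run configuration
#'
#' The fully resolved configuration of a run: prototype geometry, default
#' materials, solver settings and output options.  Interface units follow
#' laboratory convention (cm, MHz via Hz, W, deg C, mm for resolution);
#' everything is converted to SI internally.
#'
#' @return A `run_config` nested list.
#' @export
default_config <- function() {
  structure(list(
    geometry = list(d = 3.5, D = 11.7, w = 1.7, h = 8,
                    phantom_diameter = 3, phantom_height = 10,
                    tube_outer_diameter = 3.5, conductor_wall = 0.2,
                    domain_padding = 17.3, top = "closed"),
    materials = list(csv = NULL),
    em = list(frequency_hz = 434e6, amplitude_v = 1, internal_load_ohm = 50,
              tolerance = 1e-4, max_periods = 60, courant = 0.95,
              fine_mm = 1, mid_mm = 2, coarse_mm = 5),
    thermal = list(dt_s = 1, t_ext_c = 21.5, save_every_s = 10,
                   metal = "conducting"),
    experiment = list(seed = 1, power_w = 3.6, heat_s = 2400, cool_s = 600,
                      target_c = 43),
    output = list(dir = ".", vtk = FALSE)),
    class = "run_config")
}

# recursive validation against the default template; collects all problems
.validate_config <- function(cfg, tmpl, path = character()) {
  errs <- character()
  for (key in names(cfg)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(tmpl)) {
      errs <- c(errs, paste0("unknown key: ", here))
      next
    }
    if (is.list(tmpl[[key]]) && !is.null(cfg[[key]])) {
      if (!is.list(cfg[[key]])) {
        errs <- c(errs, paste0(here, " must be a section"))
      } else {
        errs <- c(errs, .validate_config(cfg[[key]], tmpl[[key]], c(path, key)))
      }
    }
  }
  errs
}

.check_config_values <- function(cfg) {
  errs <- character()
  g <- cfg$geometry
  for (key in c("d", "D", "w", "h", "phantom_diameter", "phantom_height",
                "domain_padding")) {
    if (!is.numeric(g[[key]]) || g[[key]] <= 0)
      errs <- c(errs, paste0("geometry.", key, " must be a positive number"))
  }
  if (is.numeric(g$w) && is.numeric(g$h) && g$w > 0 && g$w >= g$h)
    errs <- c(errs, "geometry.w must be smaller than geometry.h")
  if (!cfg$thermal$metal %in% c("conducting", "transparent"))
    errs <- c(errs, "thermal.metal must be 'conducting' or 'transparent'")
  if (!cfg$geometry$top %in% c("closed", "open"))
    errs <- c(errs, "geometry.top must be 'closed' or 'open'")
  if (cfg$em$frequency_hz <= 0) errs <- c(errs, "em.frequency_hz must be > 0")
  if (cfg$em$fine_mm <= 0) errs <- c(errs, "em.fine_mm must be > 0")
  if (cfg$thermal$dt_s <= 0) errs <- c(errs, "thermal.dt_s must be > 0")
  errs
}

# overlay user values onto the defaults
.merge_config <- function(tmpl, user) {
  for (key in names(user)) {
    if (is.list(tmpl[[key]]) && is.list(user[[key]]))
      tmpl[[key]] <- .merge_config(tmpl[[key]], user[[key]])
    else tmpl[key] <- list(user[[key]])       # preserves explicit NULLs
  }
  tmpl
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unset keys with the defaults of
#' [default_config()] and validates the result.  All schema violations are
#' reported together, each naming the offending key; unknown keys are
#' rejected.  An empty file yields the full default (prototype)
#' configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  tmpl <- default_config()
  errs <- .validate_config(user, tmpl)
  cfg <- .merge_config(tmpl, user)
  class(cfg) <- "run_config"
  errs <- c(errs, .check_config_values(cfg))
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  cfg
}

#' Write a configuration as YAML
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build package objects from a configuration
#'
#' @param cfg A `run_config`.
#' @return List with `geom`, `resolution`, `map`, `src`, `ctrl` ready for
#'   [run_fdtd()].
#' @export
config_objects <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  g <- cfg$geometry
  geom <- applicator_geometry(d = g$d, D = g$D, w = g$w, h = g$h,
                              phantom_diameter = g$phantom_diameter,
                              phantom_height = g$phantom_height,
                              tube_outer_diameter = g$tube_outer_diameter,
                              conductor_wall = g$conductor_wall,
                              domain_padding = g$domain_padding)
  materials <- if (!is.null(cfg$materials$csv))
    read_materials_csv(cfg$materials$csv) else default_materials()
  res <- resolution_spec(fine_mm = cfg$em$fine_mm, mid_mm = cfg$em$mid_mm,
                         coarse_mm = cfg$em$coarse_mm)
  list(geom = geom,
       resolution = res,
       map = build_material_map(geom, res, materials, top = g$top),
       src = source_spec(cfg$em$frequency_hz, cfg$em$amplitude_v,
                         cfg$em$internal_load_ohm),
       ctrl = run_ctrl(cfg$em$max_periods, cfg$em$tolerance, cfg$em$courant))
}

#' Write an axisymmetric field as a legacy-VTK rectilinear grid
#'
#' ASCII legacy format with the (r, z) plane as the X-Y plane; one or more
#' cell-data scalar arrays.
#'
#' @param path Output `.vtk` path.
#' @param map A `material_map`.
#' @param fields Named list of `nr x nz` matrices.
#' @export
write_vtk <- function(path, map, fields) {
  stopifnot(length(fields) >= 1, !is.null(names(fields)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric (r,z) cell fields", "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d 1", map$nr + 1, map$nz + 1),
               sprintf("X_COORDINATES %d double", map$nr + 1),
               paste(format(map$r_edges, digits = 9), collapse = " "),
               sprintf("Y_COORDINATES %d double", map$nz + 1),
               paste(format(map$z_edges, digits = 9), collapse = " "),
               "Z_COORDINATES 1 double", "0",
               sprintf("CELL_DATA %d", map$nr * map$nz)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", gsub("[^A-Za-z0-9_]", "_", nm)),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(format(as.vector(fields[[nm]]), digits = 9)), con)
  }
  invisible(path)
}

#' Write probe traces as CSV
#'
#' Columns `time_s`, `point_id`, `temperature_C` (explicit units in the
#' header).
#'
#' @param readings Data frame as from [sample_probes()].
#' @param path Output path.
#' @export
write_probe_csv <- function(readings, path) {
  stopifnot(all(c("time_s", "point_id", "temperature_C") %in% names(readings)))
  utils::write.csv(readings[, c("time_s", "point_id", "temperature_C")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write experiment / sweep outputs
#'
#' Writes whatever the result object carries: the sweep table, probe-trace
#' CSVs, power traces, the mid-plane image, VTK fields, plus a copy of the
#' fully resolved configuration and a short log with solver diagnostics.
#' Fails before any computation output if the directory cannot be written.
#'
#' @param results A `sweep_result`, `experiment_transients`,
#'   `experiment_steady`, `experiment_focus` or `thermal_series`.
#' @param cfg The `run_config` of the run (written alongside).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(results, cfg = default_config(), dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(dir, ".write_test")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("unwritable output path: ", dir)
  unlink(probe)
  paths <- character()
  add <- function(p) paths <<- c(paths, p)
  log <- c(sprintf("coaxtherm output written %s", format(Sys.time())))

  if (inherits(results, "sweep_result")) {
    p <- file.path(dir, "sweep.csv")
    utils::write.csv(as.data.frame(results), p, row.names = FALSE)
    add(p)
    log <- c(log, sprintf("sweep: %d rows, %d converged", nrow(results),
                          sum(results$converged)))
  } else if (inherits(results, "experiment_transients")) {
    for (k in seq_along(results$power_levels)) {
      p <- file.path(dir, sprintf("probes_%gW.csv", results$power_levels[k]))
      write_probe_csv(results$readings[[k]], p); add(p)
    }
    p <- file.path(dir, "summary.csv")
    utils::write.csv(results$summary, p, row.names = FALSE); add(p)
  } else if (inherits(results, "experiment_steady")) {
    p <- file.path(dir, "probes_steady.csv")
    write_probe_csv(results$readings, p); add(p)
    p <- file.path(dir, "power_trace.csv")
    utils::write.csv(results$power, p, row.names = FALSE); add(p)
    p <- file.path(dir, "steady_stats.csv")
    utils::write.csv(results$stats, p, row.names = FALSE); add(p)
  } else if (inherits(results, "experiment_focus")) {
    img <- results$image
    p <- file.path(dir, "ir_image.csv")
    m <- img$image; dimnames(m) <- list(sprintf("x_%g", img$x_cm),
                                        sprintf("z_%g", img$z_cm))
    utils::write.csv(m, p); add(p)
    p <- file.path(dir, "focus_decay.csv")
    utils::write.csv(results$decay, p, row.names = FALSE); add(p)
    log <- c(log, sprintf("focus: eta_T=%.4f image max=%.2f C",
                          results$eta_T, results$image_max_C))
  } else if (inherits(results, "thermal_series")) {
    p <- file.path(dir, "probes.csv")
    write_probe_csv(data.frame(time_s = rep(results$times, ncol(results$probe)),
                               point_id = rep(results$probe_points$id,
                                              each = nrow(results$probe)),
                               temperature_C = as.vector(results$probe)), p)
    add(p)
    if (isTRUE(cfg$output$vtk) && length(results$snapshots)) {
      p <- file.path(dir, "temperature_final.vtk")
      write_vtk(p, results$map, list(temperature_C = results$final_field))
      add(p)
    }
    log <- c(log, sprintf("thermal: %d steps, balance residual %.3g J",
                          length(results$times) - 1,
                          results$diag$balance_residual))
  } else stop("unsupported results object of class ", class(results)[1])

  p <- file.path(dir, "config.yaml"); write_config(cfg, p); add(p)
  p <- file.path(dir, "run.log"); writeLines(log, p); add(p)
  invisible(paths)
}
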