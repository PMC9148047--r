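#' Parametric sweep specification
#'
#' The design sweep over the inner-conductor diameter `d` and aperture width
#' `w` (12 combinations by default), with the outer diameter derived per
#' combination from the coaxial impedance constraint.
#'
#' @param d_values Inner-conductor diameters (cm).
#' @param w_values Aperture widths (cm).
#' @param h Outer-conductor height (cm).
#' @param impedance Target line impedance (Ohm).
#' @param eps_r_dielectric Dielectric relative permittivity for the
#'   impedance constraint.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(d_values = c(2.2, 3.5, 4.3),
                       w_values = c(0.7, 1.2, 1.7, 2.2),
                       h = 8, impedance = 50, eps_r_dielectric = 2.1) {
  stopifnot(all(d_values > 0), all(w_values > 0), h > 0, impedance > 0)
  structure(list(d_values = d_values, w_values = w_values, h = h,
                 impedance = impedance, eps_r_dielectric = eps_r_dielectric),
            class = "sweep_spec")
}

# geometry for one sweep combination: the PVC tube (2.5 mm wall) fills the
# bore, so the phantom diameter adapts to d as the vial holders do
.sweep_geometry <- function(d, w, spec, domain_padding = 17.3) {
  applicator_geometry(
    d = d, D = solve_outer_diameter(spec$impedance, d, spec$eps_r_dielectric),
    w = w, h = spec$h,
    phantom_diameter = d - 0.5, phantom_height = 10,
    domain_padding = domain_padding)
}

#' Location of the power-deposition focus
#'
#' @param loss A `loss_field`.
#' @param map Material map.
#' @return List with the (r, z) location (cm) of the maximum SAR inside the
#'   phantom and the ratio of the SAR at the target-volume centre to that
#'   maximum.
#' @export
sar_focus <- function(loss, map = loss$map) {
  ph <- matrix(map$materials$name[map$cell_material] == "agar gel",
               map$nr, map$nz)
  s <- loss$sar
  s[!ph] <- -Inf
  idx <- arrayInd(which.max(s), dim(s))
  list(r_cm = 100 * map$rc[idx[1]], z_cm = 100 * map$zc[idx[2]],
       center_to_max = interp_field(map, loss$sar, 0, 0) / max(s))
}

#' Run the parametric design sweep
#'
#' For every `(d, w)` combination: derive `D` from the impedance constraint,
#' rasterize, solve the harmonic field problem, and evaluate the dosimetry
#' metrics over the 1 cm^3 target volume.  Deterministic: a rerun reproduces
#' the table exactly.  A combination whose field solve does not reach steady
#' state is flagged in the `converged` column and kept in the table.
#'
#' @param spec A [sweep_spec()].
#' @param resolution A [resolution_spec()]; the sweep default is coarser
#'   (1 mm) than single-design characterization.
#' @param voi A [voi_spec()].
#' @param ctrl A [run_ctrl()].
#' @param domain_padding Air padding (cm) for the sweep geometries.
#' @param keep_profiles If `TRUE`, attach the per-combination axis profiles
#'   as an attribute `profiles`.
#' @return A `sweep_result` data frame with one row per combination:
#'   `d, w, D, eta_P, alpha, focus_r_cm, focus_z_cm, center_to_max,
#'   delivered_W, converged`.
#' @export
run_sweep <- function(spec = sweep_spec(),
                      resolution = resolution_spec(fine_mm = 1),
                      voi = voi_spec(),
                      ctrl = run_ctrl(),
                      domain_padding = 17.3,
                      keep_profiles = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  combos <- expand.grid(d = spec$d_values, w = spec$w_values,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$d, combos$w), ]
  rows <- vector("list", nrow(combos))
  profs <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    d <- combos$d[i]; w <- combos$w[i]
    row <- data.frame(d = d, w = w, D = NA_real_, eta_P = NA_real_,
                      alpha = NA_real_, focus_r_cm = NA_real_,
                      focus_z_cm = NA_real_, center_to_max = NA_real_,
                      delivered_W = NA_real_, converged = FALSE)
    res <- tryCatch({
      geom <- .sweep_geometry(d, w, spec, domain_padding)
      map <- build_material_map(geom, resolution, strict = FALSE)
      sol <- suppressWarnings(run_fdtd(map, source_spec(), ctrl))
      row$D <- geom$D
      row$converged <- sol$converged
      if (sol$converged) {
        loss <- compute_sar(sol, map)
        fc <- sar_focus(loss, map)
        row$eta_P <- eta_P(loss, voi, map)
        row$alpha <- alpha_voi(loss, voi, delivered_power(sol), map)
        row$focus_r_cm <- fc$r_cm; row$focus_z_cm <- fc$z_cm
        row$center_to_max <- fc$center_to_max
        row$delivered_W <- delivered_power(sol)
        if (keep_profiles)
          profs[[i]] <- list(
            radial = extract_profiles(loss$sar, map, "radial", normalize = TRUE),
            longitudinal = extract_profiles(loss$sar, map, "longitudinal",
                                            normalize = TRUE))
      }
      row
    }, error = function(e) {
      warning("sweep combination d=", d, ", w=", w, " failed: ",
              conditionMessage(e))
      row
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  if (keep_profiles) attr(out, "profiles") <- profs
  class(out) <- c("sweep_result", class(out))
  out
}

#' Select the design from a sweep table
#'
#' Documented selection rule balancing heating uniformity against dispersion
#' of power outside the target: among combinations whose power-heterogeneity
#' coefficient lies within `eta_band` of the minimum for their inner
#' diameter, keep those whose aperture and bore can accommodate standard
#' in vitro vials (`w >= min_w`, `d >= min_d`), and pick the one maximizing
#' the deposited-power fraction `alpha`.  The defaults return the built
#' prototype `(d = 3.5, w = 1.7)` on the default sweep.
#'
#' @param result A [run_sweep()] table.
#' @param rule List with `min_w` (cm), `min_d` (cm) and `eta_band` (absolute
#'   margin above the per-d minimum of `eta_P`).
#' @return The selected row of `result`.
#' @export
select_design <- function(result,
                          rule = list(min_w = 1.2, min_d = 3, eta_band = 0.005)) {
  stopifnot(nrow(result) >= 1)
  ok <- result$converged & is.finite(result$eta_P)
  res <- result[ok, , drop = FALSE]
  if (nrow(res) == 0) stop("empty feasible set: no converged sweep rows")
  if (nrow(res) == 1) return(res)
  eta_min <- stats::ave(res$eta_P, res$d, FUN = min)
  feas <- res$w >= rule$min_w & res$d >= rule$min_d &
    res$eta_P <= eta_min + rule$eta_band
  if (!any(feas)) stop("empty feasible set under the selection rule")
  cand <- res[feas, , drop = FALSE]
  cand[which.max(cand$alpha), , drop = FALSE]
}

#' Prototype field solution shared by the characterization experiments
#'
#' One harmonic field solve of the (by default prototype) applicator; the
#' loss field is rescaled per experiment, so all protocols reuse it.
#'
#' @param geom An [applicator_geometry()].
#' @param resolution A [resolution_spec()].
#' @param ctrl A [run_ctrl()].
#' @return List with `map`, `sol` (phasor solution) and `loss`.
#' @export
prototype_loss <- function(geom = prototype_geometry(),
                           resolution = resolution_spec(fine_mm = 1),
                           ctrl = run_ctrl()) {
  map <- build_material_map(geom, resolution)
  sol <- run_fdtd(map, source_spec(), ctrl)
  loss <- compute_sar(sol, map)
  list(map = map, sol = sol, loss = loss)
}

#' Heating-cooling transients at several power levels
#'
#' The power-characterization protocol: constant effective power for
#' `heat_duration`, then power off for `cool_duration`, one run per level,
#' all reusing a single field solve.  Fiber-optic readings are generated by
#' the virtual instrumentation.
#'
#' @param power_levels Effective powers in W.
#' @param heat_duration,cool_duration Seconds.
#' @param em A [prototype_loss()] result.
#' @param T_ext Ambient temperature (deg C).
#' @param dt Thermal time step (s).
#' @param layout A [probe_layout()].
#' @param noise A [noise_model()]; the per-level seed is offset by the level
#'   index so fibers read independent noise in each run.
#' @return An `experiment_transients` list: per-level `series`, noisy
#'   `readings` (data frames) and a `summary` table of end-of-heating and
#'   peak temperatures per probe point.
#' @export
experiment_transients <- function(power_levels = c(2.5, 3, 3.6),
                                  heat_duration = 2400, cool_duration = 600,
                                  em = prototype_loss(),
                                  T_ext = 21.5, dt = 1,
                                  layout = probe_layout(),
                                  noise = noise_model()) {
  series <- list(); readings <- list(); summ <- list()
  solver <- NULL
  for (k in seq_along(power_levels)) {
    P <- power_levels[k]
    ser <- run_transient(em$map, em$loss, power_schedule(P, heat_duration),
                         T_ext = T_ext, dt = dt, duration = heat_duration,
                         probe_points = layout$points, solver = solver)
    solver <- attr(ser, "solver")
    if (cool_duration > 0) ser <- cooling_phase(ser, cool_duration)
    nk <- noise; nk$seed <- noise$seed + 100L * k
    rd <- sample_probes(ser, layout, nk)
    heat_idx <- ser$times <= heat_duration + 1e-9
    summ[[k]] <- data.frame(
      power_W = P, point_id = layout$points$id,
      end_heating_C = ser$probe[sum(heat_idx), ],
      peak_C = apply(ser$probe[heat_idx, , drop = FALSE], 2, max),
      final_C = ser$probe[nrow(ser$probe), ])
    series[[k]] <- ser; readings[[k]] <- rd
  }
  structure(list(power_levels = power_levels, series = series,
                 readings = readings, summary = do.call(rbind, summ),
                 layout = layout),
            class = "experiment_transients")
}

#' Percent temperature reduction between two probe points
#'
#' Two conventions are in use for point-to-point comparisons: `"absolute"`
#' compares the temperatures themselves, `100 (T_ref - T_pt) / T_ref` (deg C
#' scale), and `"rise"` compares the rises above ambient,
#' `100 (dT_ref - dT_pt) / dT_ref`.
#'
#' @param T_ref,T_pt Temperatures (deg C).
#' @param T_ext Ambient (deg C), used by the rise convention.
#' @param type `"absolute"` or `"rise"`.
#' @return Percent reduction.
#' @export
temp_reduction <- function(T_ref, T_pt, T_ext = 21.5,
                           type = c("absolute", "rise")) {
  type <- match.arg(type)
  if (type == "absolute") 100 * (T_ref - T_pt) / T_ref
  else 100 * ((T_ref - T_ext) - (T_pt - T_ext)) / (T_ref - T_ext)
}

#' Closed-loop steady-state maintenance experiment
#'
#' Holds the target temperature at the VOI centre (high-power preheat, then
#' proportional-integral feedback) and reports the final-window statistics
#' at the centre (#3) and VOI-boundary (#9) points from the virtual fiber
#' readings.
#'
#' @param target Target temperature (deg C).
#' @param duration Total run time (s).
#' @param steady_window Averaging window at the end of the run (s).
#' @param controller A [temperature_controller()].
#' @param em A [prototype_loss()] result.
#' @param T_ext,dt,layout,noise As in [experiment_transients()].
#' @return An `experiment_steady` list with the `series`, noisy `readings`,
#'   realized power trace and a `stats` table (mean, sd at #3 and #9).
#' @export
experiment_steady_state <- function(target = 43, duration = 720,
                                    steady_window = 600,
                                    controller = temperature_controller(target = target),
                                    em = prototype_loss(),
                                    T_ext = 21.5, dt = 1,
                                    layout = probe_layout(),
                                    noise = noise_model()) {
  ser <- run_controlled(em$map, em$loss, controller, T_ext = T_ext, dt = dt,
                        duration = duration, probe_points = layout$points)
  rd <- sample_probes(ser, layout, noise)
  win <- ser$times >= duration - steady_window
  stats <- do.call(rbind, lapply(c(3L, 9L, 12L), function(id) {
    x <- rd$temperature_C[rd$point_id == id][win]
    data.frame(point_id = id, mean_C = mean(x), sd_C = stats::sd(x))
  }))
  structure(list(series = ser, readings = rd, stats = stats,
                 power = data.frame(time_s = ser$times, power_W = ser$power),
                 target = target, steady_window = steady_window),
            class = "experiment_steady")
}

#' Heating-focus experiment with virtual infrared imaging
#'
#' Heats the phantom at constant power, switches off, and images the
#' mid-plane after the acquisition delay (split-phantom protocol).  Reports
#' the temperature-heterogeneity coefficient over the target volume at
#' acquisition time, the image maximum, and the longitudinal decay of the
#' temperature rise beyond the VOI boundary.
#'
#' @param power Effective power (W).
#' @param heat_duration Heating time (s).
#' @param delay Acquisition delay after power-off (s).
#' @param em A [prototype_loss()] result.
#' @param T_ext,dt,noise As in [experiment_transients()].
#' @param voi A [voi_spec()].
#' @return An `experiment_focus` list: the `series`, the IR `image`, the
#'   acquisition-time field, `eta_T`, `image_max_C`, `center_C` and the
#'   longitudinal rise-reduction table.
#' @export
experiment_focus <- function(power = 5, heat_duration = 300, delay = 180,
                             em = prototype_loss(), T_ext = 21.5, dt = 1,
                             noise = noise_model(), voi = voi_spec()) {
  ser <- run_transient(em$map, em$loss, power_schedule(power, heat_duration),
                       T_ext = T_ext, dt = dt, duration = heat_duration,
                       save_every = 5)
  ser <- cooling_phase(ser, delay + 20, save_every = 5)
  img <- ir_snapshot(ser, delay = delay, noise = noise)
  fld <- .field_at_time(ser, ser$power_off_time + delay)
  map <- em$map
  zb <- voi$edge_cm / 2                       # VOI boundary on the z axis
  dT <- function(r, z) interp_field(map, fld, r / 100, z / 100) - T_ext
  decay <- data.frame(
    z_cm = c(zb, zb + 0.5, zb + 1),
    rise_C = c(dT(0, zb), dT(0, zb + 0.5), dT(0, zb + 1)))
  decay$reduction_pct <- 100 * (1 - decay$rise_C / decay$rise_C[1])
  structure(list(series = ser, image = img, field = fld,
                 eta_T = if (power > 0) eta_T(fld, voi, map) else 0,
                 image_max_C = max(img$image),
                 center_C = interp_field(map, fld, 0, 0),
                 decay = decay, power = power, delay = delay),
            class = "experiment_focus")
}
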