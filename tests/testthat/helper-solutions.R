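# Shared solver fixtures, computed once per test run.
#
# "fast" objects use a coarse 2 mm grid with reduced padding for module
# tests; "char" objects use the 1 mm characterization grid with the full
# 17.3 cm padding and back the acceptance checks.

.test_cache <- new.env(parent = emptyenv())

cache_get <- function(name, fn) {
  if (!exists(name, envir = .test_cache))
    assign(name, fn(), envir = .test_cache)
  get(name, envir = .test_cache)
}

fast_proto <- function() cache_get("fast_proto", function() {
  geom <- prototype_geometry(domain_padding = 8)
  map <- build_material_map(geom, resolution_spec(fine_mm = 2), strict = FALSE)
  sol <- suppressWarnings(run_fdtd(map, source_spec(), run_ctrl(tol = 2e-4)))
  list(geom = geom, map = map, sol = sol, loss = compute_sar(sol, map))
})

char_proto <- function() cache_get("char_proto", function() {
  prototype_loss(resolution = resolution_spec(fine_mm = 1))
})

matched_line <- function() cache_get("matched_line", function() {
  map <- uniform_coax_map(d = 3.5, D = 11.7, len = 30, fine_mm = 2)
  list(map = map, sol = run_fdtd(map, source_spec(), run_ctrl()))
})

# uniform agar cylinder with fixed surface temperature (analytic oracle)
heated_cylinder <- function(dr_m = 5e-4) {
  mats <- default_materials()
  R <- 0.015; L <- 0.3
  map <- coaxtherm:::.map_skeleton(seq(0, R, by = dr_m),
                                   seq(-L / 2, L / 2, by = 5e-3), mats)
  map$cell_material[] <- match("agar gel", mats$name)
  map$geom <- list(phantom_diameter = 200 * R, phantom_height = 100 * L,
                   conductor_wall = 0)
  class(map) <- "material_map"
  q <- 1e5
  loss <- structure(list(p_loss = matrix(q, map$nr, map$nz),
                         sar = matrix(q / 1000, map$nr, map$nz),
                         total_absorbed = q * pi * R^2 * L, map = map),
                    class = "loss_field")
  list(map = map, loss = loss, q = q, R = R, k = 0.563)
}

# 40-min heating at 3.6 W plus 10-min cooling on the characterization grid
acc_transient <- function(P) cache_get(paste0("acc_transient_", P), function() {
  em <- char_proto()
  ser <- run_transient(em$map, em$loss, power_schedule(P, 2400),
                       T_ext = 21.5, dt = 2, duration = 2400)
  cooling_phase(ser, 600)
})

acc_steady <- function() cache_get("acc_steady", function() {
  experiment_steady_state(target = 43, duration = 720, em = char_proto(),
                          noise = noise_model(seed = 42))
})

# narrow-aperture variant on the characterization grid
w07_char <- function() cache_get("w07_char", function() {
  geom <- applicator_geometry(d = 3.5, D = 11.7, w = 0.7, h = 8)
  map <- build_material_map(geom, resolution_spec(fine_mm = 1))
  sol <- run_fdtd(map, source_spec(), run_ctrl())
  list(map = map, sol = sol, loss = compute_sar(sol, map))
})

acc_sweep <- function() cache_get("acc_sweep", function() {
  run_sweep(sweep_spec(), resolution_spec(fine_mm = 1.5), keep_profiles = TRUE)
})

acc_focus <- function() cache_get("acc_focus", function() {
  em <- char_proto()
  experiment_focus(power = 5, heat_duration = 300, delay = 180, em = em,
                   noise = noise_model(seed = 42))
})
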