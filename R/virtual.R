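#' Fiber-optic thermometer layout
#'
#' Three fibers at radial offsets 0, 0.5 and 1 cm from the phantom axis,
#' each carrying measurement points on a 2 cm axial grid, 14 points in all.
#' Ids honour the documented constraints: #3 at the target-volume centre
#' (0, 0), #2/#4 at (0, +-2), #9 at (0.5, 0) and #12 at (1, 0); the id
#' ordering along fibers B and C is a package convention.
#'
#' @param spacing_cm Axial spacing of points along a fiber (cm).
#' @return A `probe_layout` with a `points` data frame (`id`, `r_cm`, `z_cm`)
#'   and the fiber description.
#' @export
probe_layout <- function(spacing_cm = 2) {
  s <- spacing_cm
  points <- rbind(
    data.frame(id = 1:5, r_cm = 0,
               z_cm = c(2 * s, s, 0, -s, -2 * s)),
    data.frame(id = c(6L, 7L, 8L, 9L, 10L), r_cm = 0.5,
               z_cm = c(2 * s, s, -s, 0, -2 * s)),
    data.frame(id = c(11L, 12L, 13L, 14L), r_cm = 1,
               z_cm = c(s, 0, -s, -2 * s)))
  structure(list(points = points,
                 fibers = data.frame(fiber = c("A", "B", "C"),
                                     r_cm = c(0, 0.5, 1)),
                 spacing_cm = spacing_cm),
            class = "probe_layout")
}

#' Measurement noise model
#'
#' Instrument accuracy mapped to Gaussian noise: fiber-optic thermometers
#' (+-0.1 degC accuracy modelled as sd 0.05), infrared camera (sd 0.2), and
#' the climate-controlled ambient 21.5 +- 1 degC.
#'
#' @param fiber_sd Fiber-optic reading noise sd (deg C).
#' @param ir_sd IR camera pixel noise sd (deg C).
#' @param ambient_mean,ambient_halfwidth Ambient temperature distribution
#'   (uniform over mean +- halfwidth, deg C).
#' @param power_rel_sd Relative sd of power-meter readings.
#' @param seed Integer seed; identical seeds give identical readings.
#' @return A `noise_model` list.
#' @export
noise_model <- function(fiber_sd = 0.05, ir_sd = 0.2,
                        ambient_mean = 21.5, ambient_halfwidth = 1,
                        power_rel_sd = 0.01, seed = 1L) {
  stopifnot(fiber_sd >= 0, ir_sd >= 0, ambient_halfwidth >= 0, power_rel_sd >= 0)
  structure(list(fiber_sd = fiber_sd, ir_sd = ir_sd,
                 ambient_mean = ambient_mean,
                 ambient_halfwidth = ambient_halfwidth,
                 power_rel_sd = power_rel_sd, seed = as.integer(seed)),
            class = "noise_model")
}

# evaluate fn with the RNG seeded from the noise model (and restored after)
.with_noise_seed <- function(noise, offset, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(noise$seed + offset)
  fn()
}

#' Sample the ambient temperature
#' @param noise A [noise_model()].
#' @return One draw of the room temperature (deg C).
#' @export
sample_ambient <- function(noise) {
  .with_noise_seed(noise, 7L, function()
    stats::runif(1, noise$ambient_mean - noise$ambient_halfwidth,
                 noise$ambient_mean + noise$ambient_halfwidth))
}

#' Virtual fiber-optic probe readings
#'
#' Adds independent Gaussian reading noise to the solver's probe traces (the
#' traces are exact bilinear samples of the temperature field at the layout
#' points).  With `fiber_sd = 0` the readings reproduce the solver output
#' exactly; a fixed seed gives bit-identical readings.
#'
#' @param series A `thermal_series` whose `probe_points` match `layout`.
#' @param layout A [probe_layout()].
#' @param noise A [noise_model()].
#' @return Data frame `time_s`, `point_id`, `temperature_C`.
#' @export
sample_probes <- function(series, layout = probe_layout(), noise = noise_model()) {
  stopifnot(inherits(series, "thermal_series"))
  pts <- layout$points
  have <- match(paste(pts$r_cm, pts$z_cm), paste(series$probe_points$r_cm,
                                                 series$probe_points$z_cm))
  if (anyNA(have))
    stop("layout error: layout points not among the recorded probe points")
  ph_r <- series$map$geom$phantom_diameter / 2
  ph_z <- series$map$geom$phantom_height / 2
  if (any(pts$r_cm > ph_r + 1e-9 | abs(pts$z_cm) > ph_z + 1e-9))
    stop("layout error: probe point outside the phantom")
  tr <- series$probe[, have, drop = FALSE]
  eps <- .with_noise_seed(noise, 11L, function()
    matrix(stats::rnorm(length(tr), 0, noise$fiber_sd), nrow(tr), ncol(tr)))
  data.frame(time_s = rep(series$times, ncol(tr)),
             point_id = rep(pts$id, each = nrow(tr)),
             temperature_C = as.vector(tr + eps))
}

#' Virtual infrared image of the phantom mid-plane
#'
#' Emulates the split-phantom measurement: the phantom is (virtually) opened
#' `delay` seconds after power-off and the mid-plane temperature map is
#' imaged.  The cooled state is read from the series snapshots (linear
#' interpolation in time), the axisymmetric half-plane is mirrored into a
#' full longitudinal section, and Gaussian pixel noise is added.
#'
#' @param series A `thermal_series` that includes a cooling phase at least
#'   `delay` seconds long (see [cooling_phase()]).
#' @param delay Seconds after power-off at which the image is acquired.
#' @param noise A [noise_model()].
#' @param pixel_mm Image pixel size (mm).
#' @return A list with `x_cm` (signed radial coordinate), `z_cm`, and the
#'   temperature `image` (matrix `length(x) x length(z)`, deg C).
#' @export
ir_snapshot <- function(series, delay = 180, noise = noise_model(),
                        pixel_mm = 1) {
  stopifnot(inherits(series, "thermal_series"))
  if (is.null(series$power_off_time))
    stop("insufficient cooling data: series has no power-off phase")
  t_img <- series$power_off_time + delay
  if (t_img > series$final_time + 1e-9)
    stop("insufficient cooling data: need ", delay, " s after power-off, have ",
         series$final_time - series$power_off_time, " s")
  fld <- .field_at_time(series, t_img)
  map <- series$map
  pr <- map$geom$phantom_diameter / 2
  ph <- map$geom$phantom_height / 2
  xs <- seq(-pr + pixel_mm / 20, pr - pixel_mm / 20, by = pixel_mm / 10)
  zs <- seq(-ph + pixel_mm / 20, ph - pixel_mm / 20, by = pixel_mm / 10)
  g <- expand.grid(x = xs, z = zs)
  img <- matrix(interp_field(map, fld, abs(g$x) / 100, g$z / 100),
                length(xs), length(zs))
  n <- .with_noise_seed(noise, 13L, function()
    matrix(stats::rnorm(length(img), 0, noise$ir_sd), nrow(img), ncol(img)))
  list(x_cm = xs, z_cm = zs, image = img + n, time_s = t_img)
}

# temperature field at an arbitrary time from snapshots (linear in time)
.field_at_time <- function(series, t) {
  st <- series$snap_times
  if (!length(st)) stop("series carries no snapshots")
  if (t >= st[length(st)] - 1e-9) {
    if (abs(t - series$final_time) < series$dt + 1e-9) return(series$final_field)
    return(series$snapshots[[length(st)]])
  }
  if (t <= st[1]) return(series$snapshots[[1]])
  i <- findInterval(t, st)
  w <- (t - st[i]) / (st[i + 1] - st[i])
  (1 - w) * series$snapshots[[i]] + w * series$snapshots[[i + 1]]
}

#' Sample perturbed phantom properties
#'
#' Lognormal perturbation of the agar-gel electrical and thermal properties
#' around their nominal values, emulating batch-to-batch variability of the
#' tissue-mimicking recipe.  Draws are strictly positive by construction;
#' `relative_sd = 0` returns the nominal values exactly.
#'
#' @param noise A [noise_model()] (supplies the seed).
#' @param relative_sd Relative standard deviation of each property.
#' @param materials Material table holding the nominal agar row.
#' @return One-row data frame of perturbed agar-gel properties.
#' @export
sample_phantom_properties <- function(noise = noise_model(), relative_sd = 0.02,
                                      materials = default_materials()) {
  stopifnot(relative_sd >= 0)
  agar <- material_lookup(materials, "agar gel")
  cols <- c("rho", "sigma", "eps_r", "cp", "k")
  if (relative_sd == 0) return(agar)
  sdl <- sqrt(log(1 + relative_sd^2))
  vals <- .with_noise_seed(noise, 17L, function()
    stats::rlnorm(length(cols), meanlog = log(unlist(agar[cols])) - sdl^2 / 2,
                  sdlog = sdl))
  agar[cols] <- as.list(vals)
  agar
}

#' Virtual power-meter trace
#'
#' Samples a power schedule at 1 s intervals and applies small multiplicative
#' reading noise, emulating the forward/reflected power-meter chain.
#'
#' @param schedule A [power_schedule()].
#' @param noise A [noise_model()].
#' @param duration Sampling duration (s); defaults to the schedule extent.
#' @param dt Sampling interval (s).
#' @return Data frame `time_s`, `power_W`.
#' @export
power_trace <- function(schedule, noise = noise_model(), duration = NULL,
                        dt = 1) {
  stopifnot(inherits(schedule, "power_schedule"))
  if (is.null(duration)) duration <- max(schedule$segments$end)
  t <- seq(0, duration, by = dt)
  p <- schedule_power(schedule, t)
  f <- .with_noise_seed(noise, 19L, function()
    stats::rnorm(length(t), 1, noise$power_rel_sd))
  data.frame(time_s = t, power_W = p * f)
}
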