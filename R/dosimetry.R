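#' Cubic volume of interest
#'
#' The target region: a cube of edge `edge_cm` centred on the axis at the
#' aperture centre `(r = 0, z = 0)`, 1 cm^3 by default.
#'
#' @param edge_cm Cube edge in cm.
#' @param center_z_cm Axial position of the cube centre in cm.
#' @param n Lattice points per edge used when sampling the axisymmetric
#'   field over the (non-axisymmetric) cube.
#' @return A `voi_spec` list.
#' @export
voi_spec <- function(edge_cm = 1, center_z_cm = 0, n = 40) {
  stopifnot(edge_cm > 0, n >= 4)
  structure(list(edge_cm = edge_cm, center_z_cm = center_z_cm, n = n),
            class = "voi_spec")
}

# equal-volume sample lattice of the cube, mapped to (r, z)
.voi_lattice <- function(voi) {
  e <- voi$edge_cm / 100
  x <- (seq_len(voi$n) - 0.5) / voi$n * e - e / 2
  g <- expand.grid(x = x, y = x, z = x)
  list(r = sqrt(g$x^2 + g$y^2),
       z = g$z + voi$center_z_cm / 100,
       w = rep(e^3 / voi$n^3, nrow(g)))
}

#' Exceedance-volume percentile of a field over a region
#'
#' Returns the largest value `v` such that the fraction of the region volume
#' where the field is `>= v` is at least `q` percent: the standard
#' temperature/dose-volume convention (P5 is a high value exceeded in 5% of
#' the volume, P95 a low value exceeded in 95%).
#'
#' @param values Field samples.
#' @param weights Volume weight of each sample (equal weights by default).
#' @param q Percent in (0, 100).
#' @return The percentile value.
#' @export
#' @examples
#' volume_percentile(c(1, 1, 1, 2), q = 5)    # 2
#' volume_percentile(c(1, 1, 1, 2), q = 95)   # 1
volume_percentile <- function(values, weights = NULL, q) {
  if (length(values) == 0) stop("empty region")
  stopifnot(q > 0, q < 100)
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values), all(weights >= 0),
            sum(weights) > 0)
  o <- order(values, decreasing = TRUE)
  cw <- cumsum(weights[o]) / sum(weights)
  values[o][which(cw >= q / 100 - 1e-12)[1]]
}

# sample a cell field over the VOI lattice
.voi_samples <- function(field, map, voi) {
  lat <- .voi_lattice(voi)
  list(v = interp_field(map, field, lat$r, lat$z), w = lat$w)
}

#' Coefficient of power heterogeneity over the VOI
#'
#' `eta_P = (P5 - P95) / P5` with P5/P95 the exceedance-volume percentiles of
#' the power-loss density over the cubic target volume; lower is more uniform.
#'
#' @param loss A `loss_field`.
#' @param voi A [voi_spec()].
#' @param map Material map (defaults to the one in `loss`).
#' @return Dimensionless heterogeneity coefficient.
#' @export
eta_P <- function(loss, voi = voi_spec(), map = loss$map) {
  s <- .voi_samples(loss$p_loss, map, voi)
  P5 <- volume_percentile(s$v, s$w, 5)
  P95 <- volume_percentile(s$v, s$w, 95)
  if (P5 <= 0) stop("undefined metric: P5 = 0 over the VOI")
  (P5 - P95) / P5
}

#' Coefficient of temperature heterogeneity over the VOI
#'
#' `eta_T = (T5 - T95) / T5` with temperatures in deg C.
#'
#' @param temps `nr x nz` temperature matrix (deg C).
#' @param voi A [voi_spec()].
#' @param map Material map.
#' @return Dimensionless heterogeneity coefficient.
#' @export
eta_T <- function(temps, voi = voi_spec(), map) {
  s <- .voi_samples(temps, map, voi)
  T5 <- volume_percentile(s$v, s$w, 5)
  T95 <- volume_percentile(s$v, s$w, 95)
  if (T5 <= 0) stop("undefined metric: T5 = 0 over the VOI")
  (T5 - T95) / T5
}

#' Fraction of supplied power deposited in the VOI
#'
#' `alpha = 100 * (VOI-integrated loss density) / supplied_power`, with the
#' effectively supplied (delivered) power as denominator.
#'
#' @param loss A `loss_field`.
#' @param voi A [voi_spec()].
#' @param supplied_power Effectively supplied power in W (> 0).
#' @param map Material map.
#' @return Percentage in `[0, 100]` for physical inputs.
#' @export
alpha_voi <- function(loss, voi = voi_spec(), supplied_power, map = loss$map) {
  stopifnot(supplied_power > 0)
  s <- .voi_samples(loss$p_loss, map, voi)
  100 * sum(s$v * s$w) / supplied_power
}

#' Field profiles along the radial and longitudinal axes
#'
#' Samples a cell field along the radial axis at the aperture-centre plane
#' (z = 0) and along the longitudinal axis (r = 0), the two axes through
#' the VOI centre.
#'
#' @param field `nr x nz` cell field.
#' @param map Material map.
#' @param axis `"radial"` or `"longitudinal"`.
#' @param normalize If `TRUE`, normalize to the value at the VOI centre.
#' @param within_cm Restrict to coordinates within this many cm of the centre
#'   (default: the phantom extent).
#' @return Data frame with `coord_cm` and `value`.
#' @export
extract_profiles <- function(field, map, axis = c("radial", "longitudinal"),
                             normalize = FALSE, within_cm = NULL) {
  axis <- match.arg(axis)
  if (axis == "radial") {
    lim <- if (is.null(within_cm)) map$geom$phantom_diameter / 2 else within_cm
    x <- map$rc[map$rc < lim / 100]
    v <- interp_field(map, field, x, rep(0, length(x)))
  } else {
    lim <- if (is.null(within_cm)) map$geom$phantom_height / 2 else within_cm
    x <- map$zc[abs(map$zc) < lim / 100]
    v <- interp_field(map, field, rep(0, length(x)), x)
  }
  if (normalize) {
    v0 <- interp_field(map, field, 0, 0)
    v <- v / v0
  }
  data.frame(coord_cm = 100 * x, value = v)
}

#' Distance at which a profile falls to a fraction of its peak
#' @param profile Data frame from [extract_profiles()].
#' @param frac Fraction of the peak (default 0.5).
#' @return Distance in cm from the peak location (positive side), `NA` if the
#'   profile never falls below the threshold.
#' @export
profile_half_distance <- function(profile, frac = 0.5) {
  v <- profile$value / max(profile$value)
  x0 <- profile$coord_cm[which.max(profile$value)]
  i <- which(v < frac & profile$coord_cm > x0)
  if (!length(i)) return(NA_real_)
  profile$coord_cm[i[1]] - x0
}

#' Dosimetry summary over the VOI
#'
#' @param loss A `loss_field`.
#' @param supplied_power Effectively supplied power (W).
#' @param voi A [voi_spec()].
#' @param map Material map.
#' @param temps Optional temperature field for `eta_T`, T5, T95.
#' @return A `metrics_result` list with P5/P95 (W/m^3), `eta_P`, `alpha`
#'   (percent), optional T5/T95/`eta_T` (deg C), and the axis profiles.
#' @export
voi_metrics <- function(loss, supplied_power, voi = voi_spec(),
                        map = loss$map, temps = NULL) {
  s <- .voi_samples(loss$p_loss, map, voi)
  out <- list(
    P5 = volume_percentile(s$v, s$w, 5),
    P95 = volume_percentile(s$v, s$w, 95),
    eta_P = eta_P(loss, voi, map),
    alpha = alpha_voi(loss, voi, supplied_power, map),
    profiles = list(
      radial = extract_profiles(loss$sar, map, "radial"),
      longitudinal = extract_profiles(loss$sar, map, "longitudinal")))
  if (!is.null(temps)) {
    st <- .voi_samples(temps, map, voi)
    out$T5 <- volume_percentile(st$v, st$w, 5)
    out$T95 <- volume_percentile(st$v, st$w, 95)
    out$eta_T <- eta_T(temps, voi, map)
  }
  class(out) <- "metrics_result"
  out
}
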