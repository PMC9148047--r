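#' @useDynLib coaxtherm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.eps0 <- 8.8541878128e-12
.mu0 <- 4e-7 * pi
.c0 <- 299792458

#' Harmonic source specification
#'
#' The applicator drive: a harmonic gap voltage applied at the feed between
#' the inner conductor and the bottom plate, with an internal (generator)
#' resistance in series.
#'
#' @param frequency Drive frequency in Hz (default 434 MHz).
#' @param amplitude Source voltage amplitude in V.
#' @param internal_load Internal source resistance in Ohm.
#' @return A `source_spec` list.
#' @export
source_spec <- function(frequency = 434e6, amplitude = 1, internal_load = 50) {
  stopifnot(frequency > 0, internal_load > 0)
  structure(list(frequency = frequency, amplitude = amplitude,
                 internal_load = internal_load), class = "source_spec")
}

#' FDTD run control
#'
#' @param max_periods Maximum number of source periods to integrate.
#' @param tol Relative cycle-to-cycle change of the feed-current amplitude
#'   below which the run is declared steady.
#' @param courant Safety factor (< 1) on the cylindrical stability limit
#'   computed from the smallest cell (the on-axis contour update is included
#'   in the limit).
#' @return A `run_ctrl` list.
#' @export
run_ctrl <- function(max_periods = 60, tol = 1e-4, courant = 0.95) {
  if (courant <= 0 || courant >= 1)
    stop("configuration error: Courant factor must lie in (0, 1)")
  stopifnot(max_periods >= 3, tol > 0)
  structure(list(max_periods = max_periods, tol = tol, courant = courant),
            class = "run_ctrl")
}

# average a per-cell quantity onto radial (Ez) edges: (nr+1) x nz
.edge_avg_r <- function(x, dr) {
  nr <- nrow(x)
  rbind(x[1, , drop = FALSE],
        (dr[-nr] * x[-nr, , drop = FALSE] + dr[-1] * x[-1, , drop = FALSE]) /
          (dr[-nr] + dr[-1]),
        x[nr, , drop = FALSE])
}

# average a per-cell quantity onto axial (Er) edges: nr x (nz+1)
.edge_avg_z <- function(x, dz) {
  nz <- ncol(x)
  cbind(x[, 1, drop = FALSE],
        t((dz[-nz] * t(x[, -nz, drop = FALSE]) + dz[-1] * t(x[, -1, drop = FALSE])) /
            (dz[-nz] + dz[-1])),
        x[, nz, drop = FALSE])
}

#' Solve the harmonic electromagnetic problem by axisymmetric FDTD
#'
#' Leap-frog integration of the transverse (Er, Ez, Hphi) field set of the
#' body-of-revolution mode 0 on the staggered non-uniform grid of `map`,
#' driven by a lumped gap source with internal resistance at the feed.  The
#' run continues until the cycle-to-cycle relative change of the feed-current
#' amplitude drops below `ctrl$tol`, after which complex phasors are
#' extracted by single-frequency projection over one full period.
#'
#' @param map A [build_material_map()] result (or [uniform_coax_map()]).
#' @param src A [source_spec()].
#' @param ctrl A [run_ctrl()].
#' @return An object of class `phasor_solution` with complex field matrices
#'   `Er` (`nr x (nz+1)`) and `Ez` (`(nr+1) x nz`), the complex feed voltage
#'   and current, `delivered_power` (W), `input_impedance`, `converged` and
#'   `periods_run`.  Non-convergence within `max_periods` gives a warning
#'   and `converged = FALSE`, never a silent result.
#' @export
run_fdtd <- function(map, src = source_spec(), ctrl = run_ctrl()) {
  stopifnot(inherits(map, "material_map"))
  nr <- map$nr; nz <- map$nz
  dr <- map$dr; dz <- map$dz; rc <- map$rc; zc <- map$zc; re <- map$r_edges

  epsc <- .eps0 * map_property(map, "eps_r")
  sigc <- map_property(map, "sigma")
  pc <- matrix(map$materials$is_pec[map$cell_material], nr, nz)

  pecEz <- rbind(pc[1, , drop = FALSE],
                 pc[-nr, , drop = FALSE] | pc[-1, , drop = FALSE],
                 pc[nr, , drop = FALSE]) | map$pec_ez
  pecEr <- cbind(pc[, 1, drop = FALSE],
                 pc[, -nz, drop = FALSE] | pc[, -1, drop = FALSE],
                 pc[, nz, drop = FALSE]) | map$pec_er

  epsEz <- .edge_avg_r(epsc, dr); sigEz <- .edge_avg_r(sigc, dr)
  epsEr <- .edge_avg_z(epsc, dz); sigEr <- .edge_avg_z(sigc, dz)

  # time step: Courant limit of the 2D cylindrical scheme (axis contour
  # update contributes the factor 2 on the radial term)
  dt_max <- ctrl$courant / (.c0 * sqrt((2 / min(dr))^2 + (1 / min(dz))^2))
  Tp <- 1 / src$frequency
  N <- as.integer(ceiling(Tp / dt_max))
  dt <- Tp / N
  omega <- 2 * pi * src$frequency

  sEz <- sigEz * dt / (2 * epsEz)
  cEzA <- (1 - sEz) / (1 + sEz); cEzB <- (dt / epsEz) / (1 + sEz)
  sEr <- sigEr * dt / (2 * epsEr)
  cErA <- (1 - sEr) / (1 + sEr); cErB <- (dt / epsEr) / (1 + sEr)

  drd <- diff(rc); dzd <- diff(zc)
  gzp <- numeric(nr + 1); gzm <- numeric(nr + 1)
  gzp[1] <- 2 / rc[1]
  gzp[2:nr] <- rc[2:nr] / (re[2:nr] * drd)
  gzm[2:nr] <- rc[1:(nr - 1)] / (re[2:nr] * drd)

  ports <- map$ports
  if (length(ports) == 0) stop("map carries no feed port")
  feed_idx <- which(vapply(ports, function(p) p$role == "feed", logical(1)))
  if (length(feed_idx) == 0) stop("map carries no feed port")
  for (k in feed_idx) {      # series split of the source over the gap cells
    ports[[k]]$Rs <- src$internal_load * ports[[k]]$frac
    ports[[k]]$Vamp <- src$amplitude * ports[[k]]$frac
  }
  p_ie <- integer(0); p_j <- integer(0)
  p_c1 <- p_c2 <- p_c3 <- p_RsA <- p_Vamp <- numeric(0)
  for (p in ports) {
    eps_e <- epsEz[p$ie, p$j]; sig_e <- sigEz[p$ie, p$j]
    s <- sig_e * dt / (2 * eps_e)
    zeta <- dt * p$dz / (2 * eps_e * p$Rs * p$A)
    p_ie <- c(p_ie, p$ie - 1L); p_j <- c(p_j, p$j - 1L)
    p_c1 <- c(p_c1, 1 - s - zeta)
    p_c2 <- c(p_c2, dt / eps_e)
    p_c3 <- c(p_c3, 1 / (1 + s + zeta))
    p_RsA <- c(p_RsA, p$Rs * p$A)
    p_Vamp <- c(p_Vamp, p$Vamp)
  }

  # first-order Mur coefficients with the local wave speed of the boundary
  # cells (exact normal-incidence absorption into a homogeneous half-space)
  cR <- .c0 / sqrt(map_property(map, "eps_r")[nr, ])
  cZlo <- .c0 / sqrt(map_property(map, "eps_r")[, 1])
  cZhi <- .c0 / sqrt(map_property(map, "eps_r")[, nz])
  murR <- (cR * dt - dr[nr]) / (cR * dt + dr[nr])
  murZlo <- (cZlo * dt - dz[1]) / (cZlo * dt + dz[1])
  murZhi <- (cZhi * dt - dz[nz]) / (cZhi * dt + dz[nz])

  # reference-plane monitors: V = -int Er dr across the annulus, I from the
  # averaged H loop around the inner conductor, both on the same z-edge
  mon <- map$monitor
  vmon_idx <- as.integer((mon$ann - 1L) + nr * (mon$je - 1L))
  vmon_w <- -dr[mon$ann]
  imon_idx <- as.integer((mon$i_cur - 1L) + nr * c(mon$je - 2L, mon$je - 1L))
  imon_w <- rep(-pi * rc[mon$i_cur], 2)   # +I flows into the device

  out <- fdtd_core(nr, nz, dr, dz, rc, re, dzd, gzp, gzm,
                   cEzA, cEzB, cErA, cErB,
                   pecEz + 0L, pecEr + 0L,
                   dt / .mu0, dt, omega, N, ctrl$max_periods, ctrl$tol,
                   p_ie, p_j, p_c1, p_c2, p_c3, p_RsA, p_Vamp,
                   vmon_idx, vmon_w, imon_idx, imon_w,
                   murR, murZlo, murZhi)

  V <- complex(real = out$Vre, imaginary = out$Vim)
  I <- complex(real = out$Ire, imaginary = out$Iim)
  if (!out$converged)
    warning("FDTD not steady after ", out$periods, " periods (last relative change ",
            signif(out$delta, 3), "); result flagged unconverged")

  sol <- list(
    Er = matrix(complex(real = out$ErRe, imaginary = out$ErIm), nr, nz + 1),
    Ez = matrix(complex(real = out$EzRe, imaginary = out$EzIm), nr + 1, nz),
    feed_voltage = V,
    feed_current = I,
    input_impedance = V / I,
    delivered_power = max(0.5 * Re(V * Conj(I)), 0),
    converged = out$converged,
    periods_run = out$periods,
    delta = out$delta,
    dt = dt, steps_per_period = N,
    map = map, src = src, ctrl = ctrl)
  class(sol) <- "phasor_solution"
  sol
}

#' @export
#' @method print phasor_solution
print.phasor_solution <- function(x, ...) {
  cat(sprintf("Phasor solution at %.0f MHz: %s after %d periods\n",
              x$src$frequency / 1e6,
              if (x$converged) "steady" else "NOT steady", x$periods_run))
  cat(sprintf("  feed V = %.4g V, |I| = %.4g A, Zin = %.2f%+.2fi Ohm\n",
              Mod(x$feed_voltage), Mod(x$feed_current),
              Re(x$input_impedance), Im(x$input_impedance)))
  cat(sprintf("  delivered power = %.4g W\n", x$delivered_power))
  invisible(x)
}

#' Power-loss density and SAR from a phasor solution
#'
#' Time-averaged ohmic loss per cell, `p_loss = sigma (|Er|^2 + |Ez|^2) / 2`
#' with the staggered field components averaged to cell centres, and the
#' specific absorption rate `sar = p_loss / rho`.
#'
#' @param sol A converged [run_fdtd()] solution.
#' @param map The material map of the run (defaults to `sol$map`).
#' @return A `loss_field`: matrices `p_loss` (W/m^3) and `sar` (W/kg) plus
#'   `total_absorbed` (W, cylindrical volume integral).
#' @export
compute_sar <- function(sol, map = sol$map) {
  stopifnot(inherits(sol, "phasor_solution"))
  if (!sol$converged)
    stop("refusing to compute SAR from an unconverged solution")
  nr <- map$nr; nz <- map$nz
  Er2 <- Mod(sol$Er)^2
  Ez2 <- Mod(sol$Ez)^2
  E2 <- (Er2[, 1:nz, drop = FALSE] + Er2[, 2:(nz + 1), drop = FALSE]) / 2 +
        (Ez2[1:nr, , drop = FALSE] + Ez2[2:(nr + 1), , drop = FALSE]) / 2
  sig <- map_property(map, "sigma")
  p <- 0.5 * sig * E2
  loss <- list(p_loss = p,
               sar = p / map_property(map, "rho"),
               total_absorbed = sum(p * cell_volumes(map)),
               map = map)
  class(loss) <- "loss_field"
  loss
}

#' Delivered power at the feed
#'
#' `0.5 Re(V conj(I))` from the feed phasors: the power that actually enters
#' the applicator (input minus reflected), the quantity the power meters of
#' the experimental chain report as "effectively supplied power".
#'
#' @param sol A [run_fdtd()] solution.
#' @return Power in W (non-negative).
#' @export
delivered_power <- function(sol) {
  stopifnot(inherits(sol, "phasor_solution"))
  sol$delivered_power
}

#' Reflection coefficient at the feed
#'
#' `S11 = 20 log10 |(Zin - Z0)/(Zin + Z0)|` with `Zin` taken from the feed
#' voltage/current phasors.
#'
#' @param sol A converged [run_fdtd()] solution.
#' @param reference_impedance Reference impedance Z0 in Ohm.
#' @param floor_db Reported floor for a perfectly matched load.
#' @return S11 in dB (<= 0).
#' @export
compute_s11 <- function(sol, reference_impedance = 50, floor_db = -120) {
  stopifnot(inherits(sol, "phasor_solution"))
  if (Mod(sol$feed_current) < 1e-12 * Mod(sol$feed_voltage))
    stop("degenerate solution: feed current is zero")
  Zin <- sol$input_impedance
  g <- Mod((Zin - reference_impedance) / (Zin + reference_impedance))
  if (g < 10^(floor_db / 20)) return(floor_db)
  20 * log10(g)
}
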