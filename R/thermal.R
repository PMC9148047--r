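#' Power schedule
#'
#' Piecewise-constant effective-power waveform driving the thermal stage.
#' Segments must be ordered and non-overlapping; outside all segments the
#' power is zero.
#'
#' @param segments Data frame with columns `start`, `end` (s) and `power` (W),
#'   or a single power value together with `duration`.
#' @param duration If `segments` is a scalar power, the length of the single
#'   segment in seconds.
#' @return A `power_schedule` object.
#' @export
#' @examples
#' power_schedule(3.6, duration = 2400)              # 40 min at 3.6 W
#' power_schedule(data.frame(start = c(0, 120), end = c(120, 720),
#'                           power = c(18, 3.2)))
power_schedule <- function(segments, duration = NULL) {
  if (is.numeric(segments) && length(segments) == 1) {
    stopifnot(!is.null(duration), duration > 0)
    segments <- data.frame(start = 0, end = duration, power = segments)
  }
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "power") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (any(segments$power < 0)) stop("powers must be >= 0")
  if (any(segments$end <= segments$start)) stop("segments must have end > start")
  if (nrow(segments) > 1 &&
      any(segments$start[-1] < segments$end[-nrow(segments)] - 1e-9))
    stop("segments must be non-overlapping and ordered")
  structure(list(segments = segments), class = "power_schedule")
}

#' Evaluate a schedule at given times
#' @param schedule A [power_schedule()].
#' @param t Times in seconds.
#' @return Power in W at each time.
#' @export
schedule_power <- function(schedule, t) {
  p <- numeric(length(t))
  for (i in seq_len(nrow(schedule$segments))) {
    s <- schedule$segments[i, ]
    p[t >= s$start & t < s$end] <- s$power
  }
  p
}

#' Rescale a loss field to a prescribed total absorbed power
#'
#' The electromagnetic stage is linear, so the loss density computed at the
#' nominal 1 V drive is rescaled so that its cylindrical volume integral
#' equals the effectively supplied power of an experiment.
#'
#' @param loss A [compute_sar()] result with `total_absorbed > 0`.
#' @param effective_power Target total absorbed power (W, >= 0).
#' @return A rescaled `loss_field`.
#' @export
scale_loss <- function(loss, effective_power) {
  stopifnot(inherits(loss, "loss_field"))
  if (loss$total_absorbed <= 0)
    stop("cannot rescale a loss field with zero total absorbed power")
  if (effective_power < 0) stop("effective_power must be >= 0")
  f <- effective_power / loss$total_absorbed
  loss$p_loss <- loss$p_loss * f
  loss$sar <- loss$sar * f
  loss$total_absorbed <- effective_power
  loss
}

# thermal properties per cell with PEC cells filled from non-metal neighbours
.thermal_props <- function(map) {
  k <- map_property(map, "k"); rho <- map_property(map, "rho")
  cp <- map_property(map, "cp")
  pec <- matrix(map$materials$is_pec[map$cell_material], map$nr, map$nz)
  it <- 0
  while (any(pec) && it < 1000) {
    idx <- which(pec, arr.ind = TRUE)
    for (q in seq_len(nrow(idx))) {
      i <- idx[q, 1]; j <- idx[q, 2]
      nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= map$nr & nb[, 2] >= 1 & nb[, 2] <= map$nz, , drop = FALSE]
      ok <- !pec[nb]
      if (any(ok)) {
        src <- nb[which(ok)[1], ]
        k[i, j] <- k[src[1], src[2]]; rho[i, j] <- rho[src[1], src[2]]
        cp[i, j] <- cp[src[1], src[2]]; pec[i, j] <- FALSE
      }
    }
    it <- it + 1
  }
  list(k = k, rho = rho, cp = cp)
}

# conservative finite-volume conduction operator on the axisymmetric grid
# with Dirichlet boundaries; returns an environment with the factorised
# implicit-Euler system.  metal = "conducting" adds in-plane conduction and
# heat capacity of the thin conductor walls (thickness geom$conductor_wall)
# along the perfect-conductor sheet faces; "transparent" ignores the sheets.
.thermal_operator <- function(map, dt, T_ext, metal = "conducting") {
  nr <- map$nr; nz <- map$nz; n <- nr * nz
  pr <- .thermal_props(map)
  k <- pr$k
  re <- map$r_edges; dr <- map$dr; dz <- map$dz; rc <- map$rc
  id <- function(i, j) i + (j - 1L) * nr

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(n)
  bvec <- numeric(n)
  bG <- numeric(n)          # total Dirichlet conductance per cell

  # radial internal faces
  for (f in seq_len(nr - 1)) {
    A <- 2 * pi * re[f + 1] * dz                     # length nz
    G <- A / (0.5 * dr[f] / k[f, ] + 0.5 * dr[f + 1] / k[f + 1, ])
    a <- id(f, seq_len(nz)); b <- id(f + 1, seq_len(nz))
    ii <- c(ii, a, b); jj <- c(jj, b, a); xx <- c(xx, -G, -G)
    diag_acc[a] <- diag_acc[a] + G; diag_acc[b] <- diag_acc[b] + G
  }
  # outer radial Dirichlet face
  A <- 2 * pi * re[nr + 1] * dz
  G <- A / (0.5 * dr[nr] / k[nr, ])
  a <- id(nr, seq_len(nz))
  diag_acc[a] <- diag_acc[a] + G; bvec[a] <- bvec[a] + G * T_ext
  bG[a] <- bG[a] + G

  # axial internal faces
  Ar <- 2 * pi * rc * dr                              # length nr
  for (f in seq_len(nz - 1)) {
    G <- Ar / (0.5 * dz[f] / k[, f] + 0.5 * dz[f + 1] / k[, f + 1])
    a <- id(seq_len(nr), f); b <- id(seq_len(nr), f + 1)
    ii <- c(ii, a, b); jj <- c(jj, b, a); xx <- c(xx, -G, -G)
    diag_acc[a] <- diag_acc[a] + G; diag_acc[b] <- diag_acc[b] + G
  }
  # bottom / top Dirichlet faces
  for (f in c(1L, nz)) {
    G <- Ar / (0.5 * dz[f] / k[, f])
    a <- id(seq_len(nr), f)
    diag_acc[a] <- diag_acc[a] + G; bvec[a] <- bvec[a] + G * T_ext
    bG[a] <- bG[a] + G
  }

  Vc <- as.vector(cell_volumes(map))
  M <- pr$rho * pr$cp * matrix(Vc, nr, nz)
  Mv <- as.vector(M)

  if (metal == "conducting" && !is.null(map$geom) &&
      (any(map$pec_ez) || any(map$pec_er))) {
    ipec <- which(map$materials$is_pec)[1]
    kb <- if (is.na(ipec)) 109 else map$materials$k[ipec]
    rcpb <- if (is.na(ipec)) 8530 * 380 else
      map$materials$rho[ipec] * map$materials$cp[ipec]
    tw <- map$geom$conductor_wall / 100
    zc <- map$zc; dzd <- diff(zc); drd <- diff(rc)
    # vertical sheets: axial conduction along r = const faces
    for (e in which(apply(map$pec_ez, 1, any))) {
      js <- which(map$pec_ez[e, -nz] & map$pec_ez[e, -1])
      for (j in js) {
        G <- kb * tw * 2 * pi * re[e] / dzd[j]
        for (cc in c(e - 1L, e)) if (cc >= 1 && cc <= nr) {
          a <- id(cc, j); b <- id(cc, j + 1L)
          ii <- c(ii, a, b); jj <- c(jj, b, a); xx <- c(xx, -G / 2, -G / 2)
          diag_acc[a] <- diag_acc[a] + G / 2; diag_acc[b] <- diag_acc[b] + G / 2
        }
      }
      jm <- which(map$pec_ez[e, ])
      m_add <- rcpb * tw * 2 * pi * re[e] * dz[jm] / 2
      for (cc in c(e - 1L, e)) if (cc >= 1 && cc <= nr)
        Mv[id(cc, jm)] <- Mv[id(cc, jm)] + m_add
    }
    # horizontal sheets (closure plates): radial conduction along z = const
    for (je in which(apply(map$pec_er, 2, any))) {
      is <- which(map$pec_er[-nr, je] & map$pec_er[-1, je])
      for (i in is) {
        G <- kb * tw * 2 * pi * re[i + 1] / drd[i]
        for (cc in c(je - 1L, je)) if (cc >= 1 && cc <= nz) {
          a <- id(i, cc); b <- id(i + 1L, cc)
          ii <- c(ii, a, b); jj <- c(jj, b, a); xx <- c(xx, -G / 2, -G / 2)
          diag_acc[a] <- diag_acc[a] + G / 2; diag_acc[b] <- diag_acc[b] + G / 2
        }
      }
      im <- which(map$pec_er[, je])
      m_add <- rcpb * tw * 2 * pi * rc[im] * dr[im] / 2
      for (cc in c(je - 1L, je)) if (cc >= 1 && cc <= nz)
        Mv[id(im, cc)] <- Mv[id(im, cc)] + m_add
    }
  }

  K <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, diag_acc), dims = c(n, n))
  A <- K + Matrix::Diagonal(n, Mv / dt)
  env <- new.env(parent = emptyenv())
  env$ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"))
  env$K <- K; env$Mv <- Mv; env$bvec <- bvec; env$bG <- bG
  env$dt <- dt; env$T_ext <- T_ext; env$n <- n; env$metal <- metal
  env
}

# bilinear interpolation weights from cell centres to points (r, z);
# coordinates are clamped to the cell-centre hull (zero-gradient at the axis)
.interp_weights <- function(map, r, z) {
  rc <- map$rc; zc <- map$zc; nr <- map$nr; nz <- map$nz
  r <- pmin(pmax(abs(r), rc[1]), rc[nr])
  z <- pmin(pmax(z, zc[1]), zc[nz])
  ir <- pmax(1L, pmin(nr - 1L, findInterval(r, rc)))
  iz <- pmax(1L, pmin(nz - 1L, findInterval(z, zc)))
  tr <- (r - rc[ir]) / (rc[ir + 1] - rc[ir])
  tz <- (z - zc[iz]) / (zc[iz + 1] - zc[iz])
  np <- length(r)
  ii <- rep(seq_len(np), 4)
  jj <- c(ir + (iz - 1L) * nr, ir + 1L + (iz - 1L) * nr,
          ir + iz * nr, ir + 1L + iz * nr)
  ww <- c((1 - tr) * (1 - tz), tr * (1 - tz), (1 - tr) * tz, tr * tz)
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(np, nr * nz))
}

#' Interpolate an axisymmetric cell field at points
#' @param map A `material_map`.
#' @param field `nr x nz` matrix of cell values.
#' @param r,z Point coordinates in metres (`r` may be negative; the field is
#'   even in `r`).
#' @return Interpolated values.
#' @export
interp_field <- function(map, field, r, z) {
  as.numeric(.interp_weights(map, r, z) %*% as.vector(field))
}

#' Transient heat conduction under a power schedule
#'
#' Integrates the conduction equation `rho cp dT/dt = div(k grad T) + P_loss`
#' on the axisymmetric grid with a conservative finite-volume discretization
#' (harmonic-mean face conductivities), unconditionally stable implicit Euler
#' stepping, temperature fixed to `T_ext` on the outer domain boundary and
#' `T = T_ext` everywhere at `t = 0`.  Perfect-conductor sheets are excluded
#' from the thermal problem (conduction passes through their faces); volumetric
#' metal cells inherit neighbouring properties.  The loss field is normalized
#' internally and scaled at each step by the schedule power, so `schedule`
#' is expressed directly as effectively supplied power in W.
#'
#' @param map A `material_map`.
#' @param loss A `loss_field` from [compute_sar()] (any overall scale).
#' @param schedule A [power_schedule()].
#' @param T_ext Ambient (and boundary/initial) temperature in deg C.
#' @param dt Time step in seconds.
#' @param duration Total simulated time in seconds.
#' @param save_every Field snapshot interval in seconds.
#' @param probe_points Data frame with `id`, `r_cm`, `z_cm` columns (defaults
#'   to [probe_layout()] points) sampled at every step.
#' @param metal `"conducting"` (default) includes in-plane conduction and
#'   heat capacity of the thin brass walls along the conductor sheet faces;
#'   `"transparent"` excludes the sheets entirely (conduction passes through
#'   unmodified).
#' @param init Optional initial temperature field (`nr x nz` matrix).
#' @param solver Optional solver context returned in a previous series (reused
#'   when `dt`, `map` and `T_ext` are unchanged).
#' @return A `thermal_series`: probe traces, power trace, snapshots, final
#'   field and an energy-balance diagnostic.
#' @export
run_transient <- function(map, loss, schedule, T_ext = 21.5, dt = 1,
                          duration, save_every = 10,
                          probe_points = probe_layout()$points,
                          metal = c("conducting", "transparent"),
                          init = NULL, solver = NULL) {
  metal <- match.arg(metal)
  stopifnot(inherits(map, "material_map"), inherits(loss, "loss_field"),
            inherits(schedule, "power_schedule"), dt > 0, duration > 0)
  nr <- map$nr; nz <- map$nz; n <- nr * nz
  if (loss$total_absorbed <= 0 &&
      any(schedule_power(schedule, seq(0, duration, by = dt)) > 0))
    stop("loss field absorbs no power; cannot apply a non-zero schedule")
  env <- if (!is.null(solver) && identical(solver$dt, dt) &&
             identical(solver$T_ext, T_ext) && identical(solver$n, n) &&
             identical(solver$metal, metal))
    solver else .thermal_operator(map, dt, T_ext, metal)

  p_unit <- if (loss$total_absorbed > 0)
    as.vector(loss$p_loss * cell_volumes(map)) / loss$total_absorbed
  else numeric(n)                                    # W per cell per W supplied

  W <- .interp_weights(map, probe_points$r_cm / 100, probe_points$z_cm / 100)
  nsteps <- as.integer(round(duration / dt))
  Tn <- if (is.null(init)) rep(T_ext, n) else as.vector(init)
  stopifnot(length(Tn) == n)

  probe <- matrix(NA_real_, nsteps + 1, nrow(probe_points))
  probe[1, ] <- as.numeric(W %*% Tn)
  times <- seq(0, by = dt, length.out = nsteps + 1)
  pow <- c(schedule_power(schedule, times[-length(times)]), 0)
  snap_times <- numeric(0); snapshots <- list()
  e_in <- 0; e_out <- 0; e0 <- sum(env$Mv * Tn)

  for (s in seq_len(nsteps)) {
    q <- p_unit * pow[s]
    rhs <- env$Mv / dt * Tn + q + env$bvec
    Tn <- as.numeric(Matrix::solve(env$ch, rhs, system = "A"))
    if (any(!is.finite(Tn)))
      stop("thermal solver produced non-finite temperatures at t = ", s * dt, " s")
    probe[s + 1, ] <- as.numeric(W %*% Tn)
    e_in <- e_in + sum(q) * dt
    e_out <- e_out + sum(env$bG * Tn - env$bvec) * dt
    if (s %% max(1L, as.integer(round(save_every / dt))) == 0) {
      snap_times <- c(snap_times, s * dt)
      snapshots[[length(snapshots) + 1]] <- matrix(Tn, nr, nz)
    }
  }
  e_stored <- sum(env$Mv * Tn) - e0
  out <- list(times = times, probe = probe, probe_points = probe_points,
              power = pow, snap_times = snap_times, snapshots = snapshots,
              final_field = matrix(Tn, nr, nz), final_time = nsteps * dt,
              map = map, loss = loss, T_ext = T_ext, dt = dt,
              diag = list(energy_in = e_in, energy_out = e_out,
                          energy_stored = e_stored,
                          balance_residual = e_in - e_out - e_stored))
  attr(out, "solver") <- env
  class(out) <- "thermal_series"
  out
}

#' @export
#' @method print thermal_series
print.thermal_series <- function(x, ...) {
  cat(sprintf("Thermal series: %.0f s in steps of %.1f s, %d probe points\n",
              x$final_time, x$dt, ncol(x$probe)))
  cat(sprintf("  T range at end: %.2f .. %.2f degC (T_ext = %.1f)\n",
              min(x$final_field), max(x$final_field), x$T_ext))
  cat(sprintf("  energy: in %.1f J, out %.1f J, stored %.1f J (residual %.2g J)\n",
              x$diag$energy_in, x$diag$energy_out, x$diag$energy_stored,
              x$diag$balance_residual))
  invisible(x)
}

#' Continue a run with the power switched off
#'
#' @param series A completed `thermal_series`.
#' @param extra_duration Additional integration time (s) at zero power.
#' @param save_every Snapshot interval (s).
#' @return A `thermal_series` covering the full (heating + cooling) history;
#'   `power_off_time` records when the supply stopped.
#' @export
cooling_phase <- function(series, extra_duration, save_every = 10) {
  stopifnot(inherits(series, "thermal_series"), extra_duration > 0)
  cool <- run_transient(series$map, series$loss,
                        power_schedule(0, duration = extra_duration),
                        T_ext = series$T_ext, dt = series$dt,
                        duration = extra_duration, save_every = save_every,
                        probe_points = series$probe_points,
                        metal = attr(series, "solver")$metal,
                        init = series$final_field,
                        solver = attr(series, "solver"))
  out <- series
  out$power_off_time <- series$final_time
  out$times <- c(series$times, series$final_time + cool$times[-1])
  out$probe <- rbind(series$probe, cool$probe[-1, , drop = FALSE])
  out$power <- c(series$power[-length(series$power)], cool$power)
  out$snap_times <- c(series$snap_times, series$final_time + cool$snap_times)
  out$snapshots <- c(series$snapshots, cool$snapshots)
  out$final_field <- cool$final_field
  out$final_time <- series$final_time + cool$final_time
  out$diag <- list(energy_in = series$diag$energy_in + cool$diag$energy_in,
                   energy_out = series$diag$energy_out + cool$diag$energy_out,
                   energy_stored = series$diag$energy_stored + cool$diag$energy_stored,
                   balance_residual = series$diag$balance_residual +
                     cool$diag$balance_residual)
  attr(out, "solver") <- attr(cool, "solver")
  out
}

#' Closed-loop temperature controller specification
#'
#' @param target Target temperature (deg C) at the probe point.
#' @param probe Probe point `c(r_cm, z_cm)` (default the target-volume centre).
#' @param kp Proportional gain (W per deg C).
#' @param ti Integral time (s).
#' @param bounds Output power clip `c(min, max)` in W.
#' @param preheat_power,preheat_time Optional scripted preheat phase (W, s)
#'   before the feedback loop engages (`mode = "pi"`), or the initial
#'   high-power plateau of the scripted waveform (`mode = "scripted"`).
#' @param hold_power Held power (W) after preheat in scripted mode.
#' @param mode `"pi"` for proportional-integral feedback, `"scripted"` for the
#'   fixed preheat-then-hold waveform.
#' @param overshoot_limit Overshoot (deg C above target) above which the run
#'   is flagged unstable.
#' @return A `temperature_controller` list.
#' @export
temperature_controller <- function(target = 43, probe = c(0, 0),
                                   kp = 5, ti = 60, bounds = c(0, 20),
                                   preheat_power = 18, preheat_time = 120,
                                   hold_power = 3.2,
                                   mode = c("pi", "scripted"),
                                   overshoot_limit = 2) {
  mode <- match.arg(mode)
  stopifnot(length(bounds) == 2, all(is.finite(bounds)), bounds[1] >= 0,
            bounds[2] > bounds[1], kp > 0, ti > 0)
  structure(list(target = target, probe = probe, kp = kp, ti = ti,
                 bounds = bounds, preheat_power = preheat_power,
                 preheat_time = preheat_time, hold_power = hold_power,
                 mode = mode, overshoot_limit = overshoot_limit),
            class = "temperature_controller")
}

#' Closed-loop (or scripted) temperature maintenance run
#'
#' Either replays the fixed experiment waveform (high power for the preheat
#' interval, then a constant hold power), or runs proportional-integral
#' feedback on the temperature at the controller's probe point, with the
#' output clipped to the controller bounds and integrator anti-windup.
#'
#' @param map,loss,T_ext,dt,duration,save_every,probe_points,metal As in
#'   [run_transient()].
#' @param controller A [temperature_controller()].
#' @return A `thermal_series` with the realized power trace and an
#'   `unstable` flag if the probe overshoot exceeded the configured limit.
#' @export
run_controlled <- function(map, loss, controller, T_ext = 21.5, dt = 1,
                           duration, save_every = 10,
                           probe_points = probe_layout()$points,
                           metal = c("conducting", "transparent")) {
  metal <- match.arg(metal)
  stopifnot(inherits(controller, "temperature_controller"),
            inherits(loss, "loss_field"), duration > 0)
  if (loss$total_absorbed <= 0) stop("loss field absorbs no power")
  nr <- map$nr; nz <- map$nz; n <- nr * nz
  env <- .thermal_operator(map, dt, T_ext, metal)
  p_unit <- as.vector(loss$p_loss * cell_volumes(map)) / loss$total_absorbed
  W <- .interp_weights(map, probe_points$r_cm / 100, probe_points$z_cm / 100)
  Wc <- .interp_weights(map, controller$probe[1] / 100, controller$probe[2] / 100)

  nsteps <- as.integer(round(duration / dt))
  Tn <- rep(T_ext, n)
  probe <- matrix(NA_real_, nsteps + 1, nrow(probe_points))
  probe[1, ] <- as.numeric(W %*% Tn)
  times <- seq(0, by = dt, length.out = nsteps + 1)
  pow <- numeric(nsteps + 1)
  integ <- 0; Tmax_probe <- -Inf
  e_in <- 0; e_out <- 0; e0 <- sum(env$Mv * Tn)

  for (s in seq_len(nsteps)) {
    t <- times[s]
    Tp <- as.numeric(Wc %*% Tn)
    Tmax_probe <- max(Tmax_probe, Tp)
    if (controller$mode == "scripted") {
      P <- if (t < controller$preheat_time) controller$preheat_power
           else controller$hold_power
    } else if (t < controller$preheat_time) {
      P <- controller$preheat_power
    } else {
      e <- controller$target - Tp
      Praw <- controller$kp * (e + integ / controller$ti)
      P <- min(max(Praw, controller$bounds[1]), controller$bounds[2])
      if (Praw > controller$bounds[1] && Praw < controller$bounds[2])
        integ <- integ + e * dt                       # anti-windup
    }
    pow[s] <- P
    q <- p_unit * P
    rhs <- env$Mv / dt * Tn + q + env$bvec
    Tn <- as.numeric(Matrix::solve(env$ch, rhs, system = "A"))
    if (any(!is.finite(Tn)))
      stop("thermal solver produced non-finite temperatures at t = ", s * dt, " s")
    probe[s + 1, ] <- as.numeric(W %*% Tn)
    e_in <- e_in + sum(q) * dt
    e_out <- e_out + sum(env$bG * Tn - env$bvec) * dt
  }
  unstable <- Tmax_probe > controller$target + controller$overshoot_limit
  if (unstable)
    warning("controller overshoot ", signif(Tmax_probe - controller$target, 3),
            " degC exceeds the configured limit; run flagged unstable")
  out <- list(times = times, probe = probe, probe_points = probe_points,
              power = pow, snap_times = numeric(0), snapshots = list(),
              final_field = matrix(Tn, nr, nz), final_time = nsteps * dt,
              map = map, loss = loss, T_ext = T_ext, dt = dt,
              controller = controller, unstable = unstable,
              diag = list(energy_in = e_in, energy_out = e_out,
                          energy_stored = sum(env$Mv * Tn) - e0,
                          balance_residual = e_in - e_out -
                            (sum(env$Mv * Tn) - e0)))
  attr(out, "solver") <- env
  class(out) <- "thermal_series"
  out
}

#' Steady-state temperature under constant power
#'
#' Direct solve of the conduction equation with the time derivative dropped;
#' used for validation against analytic solutions.
#'
#' @param map,loss,T_ext,metal As in [run_transient()].
#' @param power Constant effective power (W).
#' @return `nr x nz` temperature matrix.
#' @export
thermal_steady <- function(map, loss, power, T_ext = 21.5,
                           metal = c("conducting", "transparent")) {
  metal <- match.arg(metal)
  env <- .thermal_operator(map, dt = 1, T_ext = T_ext, metal)
  q <- as.vector(loss$p_loss * cell_volumes(map)) /
    max(loss$total_absorbed, .Machine$double.xmin) * power
  Tn <- as.numeric(Matrix::solve(env$K, q + env$bvec))
  matrix(Tn, map$nr, map$nz)
}
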