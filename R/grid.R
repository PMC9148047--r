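#' Grid resolution specification
#'
#' Controls the non-uniform axisymmetric mesh: `fine_mm` inside the bore /
#' aperture region, `mid_mm` over the rest of the applicator, and geometric
#' grading (factor `growth`) up to `coarse_mm` across the air padding.
#'
#' @param fine_mm Fine cell size (mm) in the phantom / aperture region.
#' @param mid_mm Cell size (mm) over the remaining applicator volume;
#'   default twice `fine_mm`, capped at 2 mm.
#' @param coarse_mm Maximum cell size (mm) at the domain boundary.
#' @param growth Geometric growth factor of the padding cells.
#' @return A `resolution_spec` list.
#' @export
resolution_spec <- function(fine_mm = 0.5,
                            mid_mm = min(2 * fine_mm, 2),
                            coarse_mm = 5,
                            growth = 1.3) {
  stopifnot(fine_mm > 0, mid_mm >= fine_mm, coarse_mm >= mid_mm, growth > 1)
  structure(list(fine_mm = fine_mm, mid_mm = mid_mm,
                 coarse_mm = coarse_mm, growth = growth),
            class = "resolution_spec")
}

# uniform subdivision of [x0, x1] with target spacing h (metres)
.seg_edges <- function(x0, x1, h) {
  n <- max(1L, round((x1 - x0) / h))
  seq(x0, x1, length.out = n + 1)
}

# geometrically graded widths covering length L starting from h0 up to hmax
.graded_widths <- function(L, h0, hmax, growth) {
  if (L <= 0) return(numeric(0))
  w <- numeric(0)
  h <- h0
  while (sum(w) < L) {
    w <- c(w, min(h, hmax))
    h <- h * growth
  }
  w * (L / sum(w))
}

# build one axis: 'intervals' is a data.frame(x0, x1, h) of contiguous
# uniform pieces; padding of length 'pad' is appended on the given sides.
.axis_edges <- function(intervals, pad, hmax, growth,
                        pad_low = FALSE, pad_high = FALSE) {
  edges <- intervals$x0[1]
  for (i in seq_len(nrow(intervals))) {
    e <- .seg_edges(intervals$x0[i], intervals$x1[i], intervals$h[i])
    edges <- c(edges, e[-1])
  }
  if (pad_high && pad > 0) {
    w <- .graded_widths(pad, intervals$h[nrow(intervals)], hmax, growth)
    edges <- c(edges, edges[length(edges)] + cumsum(w))
  }
  if (pad_low && pad > 0) {
    w <- .graded_widths(pad, intervals$h[1], hmax, growth)
    edges <- c(rev(edges[1] - cumsum(w)), edges)
  }
  edges
}

.map_skeleton <- function(r_edges, z_edges, materials) {
  nr <- length(r_edges) - 1L
  nz <- length(z_edges) - 1L
  list(r_edges = r_edges, z_edges = z_edges,
       rc = (r_edges[-1] + r_edges[-(nr + 1)]) / 2,
       zc = (z_edges[-1] + z_edges[-(nz + 1)]) / 2,
       dr = diff(r_edges), dz = diff(z_edges),
       nr = nr, nz = nz,
       materials = materials,
       cell_material = matrix(match("air", materials$name), nr, nz),
       pec_ez = matrix(FALSE, nr + 1L, nz),
       pec_er = matrix(FALSE, nr, nz + 1L))
}

#' Rasterize the applicator geometry onto an axisymmetric grid
#'
#' Builds the (r, z) half-plane material map: agar phantom, PVC tube, HDPE
#' annulus and air padding as cell materials, plus perfect-conductor sheets
#' on mesh faces for the inner conductor (broken along the aperture and at
#' the one-cell feed gap above the bottom plate), the outer conductor and
#' the bottom closure plate. The aperture (and target volume) centre is at
#' `(r = 0, z = 0)`; lengths are stored in metres.
#'
#' @param geom An [applicator_geometry()].
#' @param resolution A [resolution_spec()].
#' @param materials Material table, see [default_materials()].
#' @param strict If `TRUE` (default), error when any material layer is
#'   resolved by fewer than 2 cells.
#' @param top `"closed"` (default) shorts the coaxial annulus with a plate at
#'   the top, making the two line sections either side of the aperture a
#'   shorted-stub resonator (this reproduces the broad reflection dip of the
#'   device around the working band); `"open"` leaves the annulus open.
#' @return An object of class `material_map`.
#' @export
build_material_map <- function(geom,
                               resolution = resolution_spec(),
                               materials = default_materials(),
                               strict = TRUE,
                               top = c("closed", "open")) {
  top <- match.arg(top)
  stopifnot(inherits(geom, "applicator_geometry"))
  cm <- 1e-2
  hf <- resolution$fine_mm * 1e-3
  hm <- resolution$mid_mm * 1e-3
  hc <- resolution$coarse_mm * 1e-3
  pr <- geom$phantom_diameter / 2 * cm   # phantom radius
  tr <- geom$tube_outer_diameter / 2 * cm
  d2 <- geom$d / 2 * cm
  D2 <- geom$D / 2 * cm
  hw <- geom$w / 2 * cm
  hh <- geom$h / 2 * cm
  ph <- geom$phantom_height / 2 * cm
  pad <- geom$domain_padding * cm

  # --- radial axis: fine inside the bore, mid across HDPE and just outside
  rb <- sort(unique(c(0, pr, tr, d2, D2, D2 + 0.02)))
  rint <- data.frame(x0 = rb[-length(rb)], x1 = rb[-1])
  rint$h <- ifelse(rint$x1 <= d2 + 1e-12, hf, hm)
  r_edges <- .axis_edges(rint, pad, hc, resolution$growth, pad_high = TRUE)

  # --- axial axis: fine around the aperture, mid over the rest of the device
  zf <- max(hh, ph) + 0.01
  za <- hw + 0.01                         # fine band around the aperture
  zb <- sort(unique(c(-zf, -ph, -hh, -za, -hw, hw, za, hh, ph, zf)))
  zint <- data.frame(x0 = zb[-length(zb)], x1 = zb[-1])
  zint$h <- ifelse(zint$x0 >= -za - 1e-12 & zint$x1 <= za + 1e-12, hf, hm)
  z_edges <- .axis_edges(zint, pad, hc, resolution$growth,
                         pad_low = TRUE, pad_high = TRUE)

  map <- .map_skeleton(r_edges, z_edges, materials)
  map$geom <- geom
  map$resolution <- resolution

  # layer resolution check
  layers <- c(phantom_r = pr, tube_wall = tr - pr, hdpe = D2 - d2,
              aperture = geom$w * cm, phantom_z = 2 * ph)
  hs <- c(hf, hf, hm, hf, hf)
  ncell <- round(layers / hs)
  if (strict && any(layers > 0 & ncell < 2))
    stop("resolution error: layer(s) ",
         paste(names(layers)[layers > 0 & ncell < 2], collapse = ", "),
         " resolved by fewer than 2 cells; refine resolution_spec or set strict = FALSE")

  idx <- function(name) match(name, materials$name)
  RC <- matrix(map$rc, map$nr, map$nz)
  ZC <- matrix(map$zc, map$nr, map$nz, byrow = TRUE)
  m <- map$cell_material
  m[RC < D2 & RC > d2 & abs(ZC) < hh] <- idx("HDPE")
  m[RC < tr & RC > pr & abs(ZC) < ph] <- idx("PVC")
  m[RC < pr & abs(ZC) < ph] <- idx("agar gel")
  map$cell_material <- m

  near <- function(x, v) abs(x - v) < 1e-9
  ie_d <- which(near(r_edges, d2))
  ie_D <- which(near(r_edges, D2))
  je_b <- which(near(z_edges, -hh))
  stopifnot(length(ie_d) == 1, length(ie_D) == 1, length(je_b) == 1)

  zc <- map$zc
  j_feed <- which(zc > -hh)[1]
  # ~4 mm feed gap above the plate (a one-cell delta gap has a large
  # parasitic shunt capacitance; the distributed gap keeps the feed clean)
  n_gap <- max(1L, min(4L, round(0.004 / map$dz[j_feed])))
  js <- j_feed + seq_len(n_gap) - 1L
  on_ic <- zc > -hh & zc < hh & !(zc > -hw & zc < hw)
  on_ic[js] <- FALSE
  map$pec_ez[ie_d, on_ic] <- TRUE
  map$pec_ez[ie_D, zc > -hh & zc < hh] <- TRUE
  map$pec_er[map$rc > d2 & map$rc < D2, je_b] <- TRUE
  if (top == "closed") {
    je_t <- which(near(z_edges, hh))
    map$pec_er[map$rc > d2 & map$rc < D2, je_t] <- TRUE
  }

  drd <- map$rc[ie_d] - map$rc[ie_d - 1]
  frac <- map$dz[js] / sum(map$dz[js])
  map$ports <- lapply(seq_along(js), function(k)
    list(ie = ie_d, j = js[k], r = d2,
         dz = map$dz[js[k]], A = 2 * pi * d2 * drd,
         Rs = NA_real_, Vamp = NA_real_, frac = frac[k], role = "feed"))
  # V/I reference plane on the feed line, outside the evanescent near-field
  # of the gap: line voltage integrated across the annulus, current loop
  # around the inner conductor, both on the same z-edge
  z_mon <- -hh + min(0.01, (hh - hw) / 3)
  map$monitor <- list(je = which.min(abs(z_edges - z_mon)),
                      i_cur = ie_d,
                      ann = which(map$rc > d2 & map$rc < D2))
  class(map) <- "material_map"
  map
}

#' Uniform coaxial line section (validation geometry)
#'
#' A straight shielded coax of length `len` with both ends closed by plates:
#' a feed gap at the bottom and a lumped resistive load `load_R` at the top.
#' Used to validate the field solver against the analytic line impedance.
#'
#' @param d,D Conductor diameters (cm).
#' @param len Line length (cm).
#' @param dielectric Name of the filling material.
#' @param termination `"match"` runs the line straight into the absorbing
#'   boundary (a reflection-free infinite line); `"load"` closes the far end
#'   with a plate and a lumped resistor `load_R` across a one-cell gap.
#' @param load_R Termination resistance (Ohm); default the analytic `Z0`.
#' @param fine_mm Cell size (mm).
#' @param materials Material table.
#' @return A `material_map` with a feed port (and a load port for
#'   `termination = "load"`).
#' @export
uniform_coax_map <- function(d = 3.5, D = 11.7, len = 30,
                             dielectric = "HDPE",
                             termination = c("match", "load"),
                             load_R = NULL,
                             fine_mm = 2,
                             materials = default_materials()) {
  termination <- match.arg(termination)
  cm <- 1e-2
  h <- fine_mm * 1e-3
  d2 <- d / 2 * cm; D2 <- D / 2 * cm; L <- len * cm
  eps_r <- material_lookup(materials, dielectric)$eps_r
  if (is.null(load_R)) load_R <- coax_impedance(D, d, eps_r)

  rb <- c(0, d2, D2, D2 + 0.02)
  rint <- data.frame(x0 = rb[-4], x1 = rb[-1], h = h)
  r_edges <- .axis_edges(rint, 0.05, 5e-3, 1.3, pad_high = TRUE)
  zint <- data.frame(x0 = 0, x1 = L, h = h)
  z_edges <- .axis_edges(zint, 0.05, 5e-3, 1.3, pad_low = TRUE,
                         pad_high = (termination == "load"))

  map <- .map_skeleton(r_edges, z_edges, materials)
  RC <- matrix(map$rc, map$nr, map$nz)
  ZC <- matrix(map$zc, map$nr, map$nz, byrow = TRUE)
  map$cell_material[RC > d2 & RC < D2 & ZC > 0 & ZC < L] <-
    match(dielectric, materials$name)

  near <- function(x, v) abs(x - v) < 1e-9
  ie_d <- which(near(r_edges, d2))
  ie_D <- which(near(r_edges, D2))
  je0 <- which(near(z_edges, 0))
  zc <- map$zc
  j_feed <- which(zc > 0)[1]
  n_gap <- max(1L, min(4L, round(0.004 / map$dz[j_feed])))
  js <- j_feed + seq_len(n_gap) - 1L
  on_ic <- zc > 0 & zc < L
  on_ic[js] <- FALSE
  drd <- map$rc[ie_d] - map$rc[ie_d - 1]
  A <- 2 * pi * d2 * drd
  frac <- map$dz[js] / sum(map$dz[js])
  ports <- lapply(seq_along(js), function(k)
    list(ie = ie_d, j = js[k], r = d2, dz = map$dz[js[k]],
         A = A, Rs = NA_real_, Vamp = NA_real_, frac = frac[k], role = "feed"))
  if (termination == "load") {
    je1 <- which(near(z_edges, L))
    jl <- rev(which(zc < L))[1] - seq_len(n_gap) + 1L
    on_ic[jl] <- FALSE
    map$pec_er[map$rc > d2 & map$rc < D2, je1] <- TRUE
    lfrac <- map$dz[jl] / sum(map$dz[jl])
    for (k in seq_along(jl))
      ports[[length(ports) + 1L]] <- list(ie = ie_d, j = jl[k], r = d2,
                                          dz = map$dz[jl[k]], A = A,
                                          Rs = load_R * lfrac[k], Vamp = 0,
                                          frac = lfrac[k], role = "load")
  }
  map$pec_ez[ie_d, on_ic] <- TRUE
  map$pec_ez[ie_D, zc > 0 & zc < L] <- TRUE
  map$pec_er[map$rc > d2 & map$rc < D2, je0] <- TRUE
  map$ports <- ports
  map$monitor <- list(je = which.min(abs(z_edges - min(0.01, L / 3))),
                      i_cur = ie_d,
                      ann = which(map$rc > d2 & map$rc < D2))
  map$geom <- NULL
  class(map) <- "material_map"
  map
}

#' Per-cell material property matrix
#' @param map A `material_map`.
#' @param prop One of `"rho"`, `"sigma"`, `"eps_r"`, `"cp"`, `"k"`.
#' @return `nr x nz` numeric matrix.
#' @export
map_property <- function(map, prop) {
  v <- map$materials[[prop]]
  pec <- map$materials$is_pec
  if (prop == "sigma") v[pec] <- 0
  if (prop == "eps_r") v[pec] <- 1
  matrix(v[map$cell_material], map$nr, map$nz)
}

#' Cell volumes of the axisymmetric grid
#' @param map A `material_map`.
#' @return `nr x nz` matrix of full-revolution volumes `2 pi r dr dz` (m^3).
#' @export
cell_volumes <- function(map) {
  outer(2 * pi * map$rc * map$dr, map$dz)
}

#' Rasterized material volumes
#' @param map A `material_map`.
#' @return Named vector of total volume per material (m^3).
#' @export
map_volumes <- function(map) {
  V <- cell_volumes(map)
  tapply(as.vector(V), map$materials$name[as.vector(map$cell_material)], sum)
}

#' @export
#' @method print material_map
print.material_map <- function(x, ...) {
  cat(sprintf("Axisymmetric material map: %d x %d cells, r <= %.3f m, z in [%.3f, %.3f] m\n",
              x$nr, x$nz, max(x$r_edges), min(x$z_edges), max(x$z_edges)))
  tab <- table(x$materials$name[x$cell_material])
  for (n in names(tab)) cat(sprintf("  %-10s %6d cells\n", n, tab[[n]]))
  invisible(x)
}
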