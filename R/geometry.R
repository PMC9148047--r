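#' Characteristic impedance of a coaxial line
#'
#' Simplified TEM-line relation `Z = 138 * log10(D/d) / sqrt(eps_r)` used to
#' size the applicator so that it presents a 50 Ohm load to the generator.
#'
#' @param D Inner diameter of the outer conductor (cm).
#' @param d Outer diameter of the inner conductor (cm). Must satisfy `D > d > 0`.
#' @param eps_r Relative permittivity of the dielectric filling (>= 1).
#'   Defaults to HDPE (2.1).
#' @return Characteristic impedance in Ohm.
#' @seealso [solve_outer_diameter()] for the inverse relation.
#' @export
#' @examples
#' coax_impedance(11.7, 3.5, 2.1)  # ~50 Ohm, the prototype sizing
coax_impedance <- function(D, d, eps_r = 2.1) {
  if (any(!is.finite(D)) || any(!is.finite(d)) || any(d <= 0) || any(D < d))
    stop("invalid coax geometry: need D >= d > 0 (got D=", D[1], ", d=", d[1], ")")
  if (any(eps_r < 1)) stop("eps_r must be >= 1")
  138 * log10(D / d) / sqrt(eps_r)
}

#' Outer-conductor diameter for a target impedance
#'
#' Inverts the coaxial impedance relation: `D = d * 10^(Z * sqrt(eps_r) / 138)`.
#'
#' @param Z Target characteristic impedance (Ohm, >= 0).
#' @param d Inner-conductor outer diameter (cm, > 0).
#' @inheritParams coax_impedance
#' @return Outer-conductor inner diameter D in cm.
#' @export
#' @examples
#' round(solve_outer_diameter(50, 3.5, 2.1), 1)  # 11.7 cm
solve_outer_diameter <- function(Z, d, eps_r = 2.1) {
  if (any(Z < 0)) stop("Z must be >= 0")
  if (any(d <= 0)) stop("d must be > 0")
  if (any(eps_r < 1)) stop("eps_r must be >= 1")
  d * 10^(Z * sqrt(eps_r) / 138)
}

#' Parametric applicator / phantom geometry
#'
#' Describes the open-ended coaxial TEM applicator: a hollow inner conductor
#' of outer diameter `d` with a circumferential aperture of width `w` centred
#' at `z = 0`, an outer conductor of inner diameter `D` and height `h` closed
#' at the bottom by a plate carrying the feed gap, an HDPE-filled annulus
#' between the conductors, and a cylindrical agar phantom in a PVC tube
#' inserted in the bore. All lengths in cm; `z = 0` is the aperture centre
#' (and the centre of the target volume), `z` increases upward.
#'
#' Conductors are represented as zero-thickness perfectly conducting sheets
#' at radii d/2 and D/2 when rasterized; `conductor_wall` is recorded
#' as the nominal construction thickness but is not meshed.
#'
#' @param d Inner-conductor outer diameter (cm).
#' @param D Outer-conductor inner diameter (cm); default solves the 50 Ohm
#'   constraint for HDPE.
#' @param w Aperture width (cm), `0 < w < h`.
#' @param h Outer-conductor height (cm).
#' @param phantom_diameter,phantom_height Agar phantom dimensions (cm).
#' @param tube_outer_diameter PVC tube outer diameter (cm); defaults to `d`
#'   so the tube fills the bore.
#' @param tube_wall PVC tube wall thickness (cm); default fills the space
#'   between phantom and bore.
#' @param conductor_wall Nominal brass wall thickness (cm, recorded only).
#' @param domain_padding Air padding between applicator and computational
#'   domain boundary (cm).
#' @return An object of class `applicator_geometry` (a named list).
#' @export
applicator_geometry <- function(d = 3.5,
                                D = solve_outer_diameter(50, d, 2.1),
                                w = 1.7,
                                h = 8,
                                phantom_diameter = 3,
                                phantom_height = 10,
                                tube_outer_diameter = d,
                                tube_wall = (tube_outer_diameter - phantom_diameter) / 2,
                                conductor_wall = 0.2,
                                domain_padding = 17.3) {
  g <- list(d = d, D = D, w = w, h = h,
            phantom_diameter = phantom_diameter,
            phantom_height = phantom_height,
            tube_outer_diameter = tube_outer_diameter,
            tube_wall = tube_wall,
            conductor_wall = conductor_wall,
            domain_padding = domain_padding)
  lens <- unlist(g[c("d", "D", "w", "h", "phantom_diameter", "phantom_height",
                     "tube_outer_diameter", "domain_padding")])
  if (any(!is.finite(unlist(g))) || any(lens <= 0))
    stop("all geometry lengths must be positive and finite")
  if (!(D > d)) stop("invalid geometry: need D > d")
  if (!(d >= tube_outer_diameter)) stop("invalid geometry: need d >= tube_outer_diameter")
  if (!(tube_outer_diameter >= phantom_diameter))
    stop("invalid geometry: need tube_outer_diameter >= phantom_diameter")
  if (tube_wall < 0) stop("invalid geometry: tube_wall < 0")
  if (!(w > 0 && w < h)) stop("invalid geometry: need 0 < w < h")
  structure(g, class = "applicator_geometry")
}

#' Built prototype geometry
#'
#' The dimensions of the realized applicator: `d = 3.5` cm, `w = 1.7` cm,
#' `h = 8` cm and `D = 11.7` cm from the 50 Ohm constraint with HDPE.
#'
#' @param ... Overrides passed to [applicator_geometry()].
#' @return An `applicator_geometry` object.
#' @export
prototype_geometry <- function(...) {
  applicator_geometry(d = 3.5, D = 11.7, w = 1.7, h = 8, ...)
}

#' @export
#' @method print applicator_geometry
print.applicator_geometry <- function(x, ...) {
  cat("Coaxial TEM applicator geometry (cm):\n")
  cat(sprintf("  inner conductor d = %.2f, outer conductor D = %.2f (Z ~ %.1f Ohm)\n",
              x$d, x$D, coax_impedance(x$D, x$d, 2.1)))
  cat(sprintf("  aperture w = %.2f, height h = %.2f\n", x$w, x$h))
  cat(sprintf("  phantom %.1f x %.1f, tube outer %.2f (wall %.2f)\n",
              x$phantom_diameter, x$phantom_height,
              x$tube_outer_diameter, x$tube_wall))
  cat(sprintf("  domain padding %.1f\n", x$domain_padding))
  invisible(x)
}
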