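#' Material property record
#'
#' @param name Material name.
#' @param rho Mass density (kg/m^3, > 0).
#' @param sigma Electrical conductivity (S/m, >= 0).
#' @param eps_r Relative permittivity (>= 1).
#' @param cp Specific heat capacity (J/(kg K), > 0).
#' @param k Thermal conductivity (W/(m K), > 0).
#' @param is_pec Perfect-electric-conductor flag; the electrical columns of a
#'   PEC material are ignored by the field solver.
#' @return One-row data frame with the material columns.
#' @export
material_properties <- function(name, rho, sigma, eps_r, cp, k, is_pec = FALSE) {
  if (rho <= 0) stop("rho must be > 0")
  if (!is_pec && sigma < 0) stop("sigma must be >= 0")
  if (!is_pec && eps_r < 1) stop("eps_r must be >= 1")
  if (cp <= 0) stop("cp must be > 0")
  if (k <= 0) stop("k must be > 0")
  data.frame(name = name, rho = rho, sigma = sigma, eps_r = eps_r,
             cp = cp, k = k, is_pec = is_pec, stringsAsFactors = FALSE)
}

#' Default material table
#'
#' Electrical and thermal properties of the simulated media: HDPE dielectric,
#' PVC phantom holder, salt-doped agar gel with muscle-like properties at
#' 434 MHz, brass (modelled as a perfect electric conductor) and air
#' (textbook values; air occurs only in the padding regions).
#'
#' @return Data frame with columns `name, rho, sigma, eps_r, cp, k, is_pec`.
#' @export
#' @examples
#' default_materials()
default_materials <- function() {
  rbind(
    material_properties("HDPE",     950, 1e-5,  2.1, 1900, 0.5),
    material_properties("PVC",     1380, 1e-4,  3,   1250, 0.2),
    material_properties("agar gel", 1000, 0.755, 74,  4181, 0.563),
    material_properties("brass",   8530, 0,     1,   380,  109, is_pec = TRUE),
    material_properties("air",      1.2, 0,     1,   1005, 0.026)
  )
}

#' Look up one material by name
#' @param materials Material table as from [default_materials()].
#' @param name Material name.
#' @return One-row data frame.
#' @export
material_lookup <- function(materials, name) {
  i <- match(name, materials$name)
  if (is.na(i)) stop("unknown material: ", name)
  materials[i, , drop = FALSE]
}

#' Write / read a material table as CSV
#'
#' The CSV carries the property columns in the conventional order
#' `rho, sigma, eps_r, cp, k` after the name, plus the PEC flag.
#'
#' @param materials Material table.
#' @param path File path.
#' @return `read_materials_csv` returns the validated table.
#' @export
write_materials_csv <- function(materials, path) {
  utils::write.csv(materials[, c("name", "rho", "sigma", "eps_r", "cp", "k", "is_pec")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_materials_csv
#' @export
read_materials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "rho", "sigma", "eps_r", "cp", "k", "is_pec")
  if (!all(need %in% names(df)))
    stop("material CSV must have columns: ", paste(need, collapse = ", "))
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    material_properties(df$name[i], df$rho[i], df$sigma[i], df$eps_r[i],
                        df$cp[i], df$k[i], as.logical(df$is_pec[i]))))
  out
}
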