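#' Model parameters for hydrolytic chain-scission kinetics
#'
#' Bundles the kinetic and physical constants of the degradation model. All
#' quantities are in CGS-based polymer-engineering units (concentrations in
#' mol cm^-3, diffusivities in cm^2 s^-1, molar masses in g mol^-1). Defaults
#' correspond to a 70:30 poly(L-lactide-co-caprolactone) thin film.
#'
#' @param kd degradation kinetic constant, cm^6 mol^-2 s^-1. The hydrolysis
#'   rate is third order: proportional to water concentration, bond
#'   concentration and chain concentration (autocatalysis by acid chain ends).
#' @param DM0 pristine monomer diffusivity, cm^2 s^-1.
#' @param Dolig0 pristine oligomer diffusivity, cm^2 s^-1 (dimer to nonamer).
#' @param DW0 pristine water diffusivity, cm^2 s^-1.
#' @param Mmon molar mass of the repeating unit, g mol^-1.
#' @param rho_pol polymer density, g cm^-3.
#' @param CW_surface water concentration imposed at the film surface,
#'   mol cm^-3. Default 0.0555 is the molar concentration of pure water.
#' @param Mn_ref number-average molecular weight before degradation onset,
#'   g mol^-1; reference for the degradation-enhanced diffusivity law.
#'
#' @return An object of class \code{model_params}.
#' @seealso [effective_diffusivity()], [reaction_sources()], [init_uniform()]
#' @export
#' @examples
#' p <- model_params(kd = 3.85e-5, Mn_ref = 406000)
#' p
model_params <- function(kd = 3.85e-5,
                         DM0 = 1e-10,
                         Dolig0 = 1e-10,
                         DW0 = 1e-8,
                         Mmon = 90.08,
                         rho_pol = 1.2,
                         CW_surface = 0.0555,
                         Mn_ref = 406000) {
  for (nm in c("kd", "DM0", "Dolig0", "DW0", "Mmon", "rho_pol",
               "CW_surface", "Mn_ref")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (kd < 0) stop("'kd' must be >= 0", call. = FALSE)
  for (nm in c("DM0", "Dolig0", "DW0", "Mmon", "rho_pol", "CW_surface",
               "Mn_ref")) {
    if (get(nm) <= 0)
      stop("'", nm, "' must be strictly positive", call. = FALSE)
  }
  if (Mn_ref < Mmon)
    stop("'Mn_ref' must be at least one repeating unit ('Mmon')",
         call. = FALSE)
  structure(list(kd = kd, DM0 = DM0, Dolig0 = Dolig0, DW0 = DW0,
                 Mmon = Mmon, rho_pol = rho_pol,
                 CW_surface = CW_surface, Mn_ref = Mn_ref),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Degradation model parameters\n")
  cat(sprintf("  kd         %.4g cm^6 mol^-2 s^-1\n", x$kd))
  cat(sprintf("  DM0        %.3g cm^2 s^-1\n", x$DM0))
  cat(sprintf("  Dolig0     %.3g cm^2 s^-1\n", x$Dolig0))
  cat(sprintf("  DW0        %.3g cm^2 s^-1\n", x$DW0))
  cat(sprintf("  Mmon       %.4g g mol^-1\n", x$Mmon))
  cat(sprintf("  rho_pol    %.3g g cm^-3\n", x$rho_pol))
  cat(sprintf("  CW_surface %.4g mol cm^-3\n", x$CW_surface))
  cat(sprintf("  Mn_ref     %.6g g mol^-1\n", x$Mn_ref))
  invisible(x)
}

#' Spatial grid over the film half-thickness
#'
#' The film is degraded symmetrically, so only the half-thickness is
#' discretised: node 1 sits at the film centre (symmetry plane, x = 0) and
#' node \code{n_nodes} at the surface. Nodes are uniformly spaced.
#'
#' @param half_thickness half film thickness, cm. Default 27.5e-4 cm
#'   (half of a 55 micrometre film).
#' @param n_nodes number of grid nodes (>= 3).
#' @return An object of class \code{grid_spec} with fields
#'   \code{half_thickness}, \code{n_nodes}, \code{x} (node positions, cm)
#'   and \code{dx} (spacing, cm).
#' @export
#' @examples
#' grid_spec(n_nodes = 51)
grid_spec <- function(half_thickness = 27.5e-4, n_nodes = 51L) {
  if (!is.numeric(half_thickness) || length(half_thickness) != 1L ||
      !is.finite(half_thickness) || half_thickness <= 0)
    stop("'half_thickness' must be a single positive number", call. = FALSE)
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 3L)
    stop("'n_nodes' must be an integer >= 3", call. = FALSE)
  x <- seq(0, half_thickness, length.out = n_nodes)
  structure(list(half_thickness = half_thickness, n_nodes = n_nodes,
                 x = x, dx = half_thickness / (n_nodes - 1L)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "Film half-thickness grid: %d nodes over %.4g cm (dx = %.4g cm)\n",
    x$n_nodes, x$half_thickness, x$dx))
  invisible(x)
}
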