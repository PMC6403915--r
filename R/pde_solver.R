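# State layout: node-major vector, 13 entries per node in the order
# CW, CM, C2..C9, mu0, mu1, mu2. Adjacent nodes are adjacent blocks, so the
# Jacobian is banded with half-bandwidth 2*13; lsoda exploits this.
.NSPEC <- 13L
.pack_state <- function(st) {
  as.vector(t(cbind(st$CW, st$CM, st$C, st$mu0, st$mu1, st$mu2)))
}
.unpack_state <- function(y) {
  mat <- matrix(y, ncol = .NSPEC, byrow = TRUE)
  list(CW = mat[, 1L], CM = mat[, 2L], C = mat[, 3:10, drop = FALSE],
       mu0 = mat[, 11L], mu1 = mat[, 12L], mu2 = mat[, 13L])
}

#' Boundary conditions for the film model
#'
#' Node 1 is the film centre and always a symmetry (zero-flux) plane. At the
#' surface the defaults are the standard thin-film hydrolysis setup: water
#' held at its bath concentration (Dirichlet) and a perfect sink
#' (concentration zero) for monomer and the mobile oligomers. A fully sealed
#' film (zero flux for every species, used for conservation checks) is
#' obtained with both arguments \code{"zeroflux"}.
#'
#' @param water \code{"dirichlet"} (surface water fixed at
#'   \code{params$CW_surface}) or \code{"zeroflux"}.
#' @param species \code{"sink"} (monomer and oligomers held at zero at the
#'   surface) or \code{"zeroflux"}.
#' @return list of class \code{boundary_spec}.
#' @export
boundary_conditions <- function(water = c("dirichlet", "zeroflux"),
                                species = c("sink", "zeroflux")) {
  structure(list(water = match.arg(water), species = match.arg(species)),
            class = "boundary_spec")
}

# Divergence of D grad C on the uniform half-film grid, conservative flux
# form with arithmetic-mean face diffusivities. Left boundary: mirror ghost
# (zero flux). Right boundary: mirror ghost, or an antisymmetric ghost
# through the Dirichlet value when `right_value` is given.
.div_flux <- function(C, D, dx, right_value = NULL) {
  m <- length(C)
  Df <- (D[-m] + D[-1L]) / 2
  Fl <- Df * diff(C) / dx                  # flux at faces 1.5 .. (m-0.5)
  div <- numeric(m)
  if (m > 2L) div[2:(m - 1L)] <- diff(Fl) / dx
  div[1L] <- 2 * Fl[1L] / dx
  if (is.null(right_value)) {
    div[m] <- -2 * Fl[m - 1L] / dx
  } else {
    ghost <- 2 * right_value - C[m - 1L]
    Fr <- (D[m] + D[m - 1L]) / 2 * (ghost - C[m]) / dx
    div[m] <- (Fr - Fl[m - 1L]) / dx
  }
  div
}

# Time derivative of the packed state; shared by assemble_rhs() and the
# integrator. `st` is an unpacked list; returns a list of the same shape.
.rhs_field <- function(st, params, grid, boundary, diffusion = TRUE) {
  src <- reaction_sources(st, params)
  m <- length(st$CW)
  if (!diffusion || m == 1L) {
    return(list(CW = src$CW, CM = src$CM, C = src$C,
                mu0 = src$mu0, mu1 = src$mu1, mu2 = src$mu2))
  }
  dx <- grid$dx
  # local Mn for the diffusivity law; fully degraded nodes (mu0 -> 0 with
  # mu1 -> 0) get the fully-degraded (maximal) diffusivity
  Mn_loc <- ifelse(st$mu0 > 0, st$mu1 / st$mu0 * params$Mmon, 0)
  DW <- effective_diffusivity(params$DW0, Mn_loc, params$Mn_ref)
  DM <- effective_diffusivity(params$DM0, Mn_loc, params$Mn_ref)
  Do <- effective_diffusivity(params$Dolig0, Mn_loc, params$Mn_ref)

  w_bc <- if (boundary$water == "dirichlet") params$CW_surface else NULL
  s_bc <- if (boundary$species == "sink") 0 else NULL
  div_W <- .div_flux(st$CW, DW, dx, w_bc)
  div_M <- .div_flux(st$CM, DM, dx, s_bc)
  div_C <- matrix(0, m, 8L)
  for (j in 1:8) div_C[, j] <- .div_flux(st$C[, j], Do, dx, s_bc)

  # moment transport: summed species divergences weighted by n^0, n^1, n^2
  nlen <- 2:9
  tr0 <- div_M + rowSums(div_C)
  tr1 <- div_M + div_C %*% nlen
  tr2 <- div_M + div_C %*% nlen^2

  dCW <- div_W + src$CW
  dCM <- div_M + src$CM
  dC <- div_C + src$C
  # Dirichlet nodes are pinned: their values are set by integrate_film()
  if (!is.null(w_bc)) dCW[m] <- 0
  if (!is.null(s_bc)) { dCM[m] <- 0; dC[m, ] <- 0 }
  list(CW = dCW, CM = dCM, C = dC,
       mu0 = as.numeric(tr0 + src$mu0),
       mu1 = as.numeric(tr1 + src$mu1),
       mu2 = as.numeric(tr2 + src$mu2))
}

#' Assemble the method-of-lines right-hand side
#'
#' Spatially discretised time derivative of the full field state: centred
#' finite differences in conservative flux form for every diffusible species
#' (water, monomer, dimer..nonamer), with face diffusivities taken as the
#' arithmetic mean of the node values of the degradation-dependent
#' diffusivity, plus the scission reaction sources. The moments have no
#' boundary conditions of their own: their transport is the sum of the
#' species' divergence terms weighted by chain length to the power 0, 1, 2.
#'
#' @param state a \code{field_state} on \code{grid}.
#' @param params a \code{model_params}.
#' @param grid a \code{grid_spec}.
#' @param boundary a [boundary_conditions()] list.
#' @param diffusion set \code{FALSE} to drop all transport terms (the
#'   result then equals [reaction_sources()] exactly).
#' @return list with the same components as the state: time derivatives,
#'   mol cm^-3 s^-1.
#' @export
assemble_rhs <- function(state, params, grid,
                         boundary = boundary_conditions(),
                         diffusion = TRUE) {
  if (state$n_nodes != grid$n_nodes && diffusion)
    stop("state and grid disagree on the number of nodes", call. = FALSE)
  .rhs_field(state, params, grid, boundary, diffusion)
}

#' Integrate the film degradation model
#'
#' Stiff time integration (method of lines, \code{deSolve::lsoda} with a
#' banded Jacobian) of the reaction-diffusion system over the film
#' half-thickness. Device-level averages at each output time are computed by
#' applying the moment-to-averages map to the trapezoidal integrals of the
#' moments over the domain.
#'
#' In well-mixed mode (\code{well_mixed = TRUE}) the state has a single node
#' and no transport; optionally the water concentration is held fixed at
#' \code{fixed_CW}, which is the configuration used for parameter fitting:
#' for a 55 micrometre film, water equilibrates within hours while
#' degradation takes months, so the film is water-saturated on the timescale
#' that matters.
#'
#' @param init a \code{field_state} (one node in well-mixed mode).
#' @param params a \code{model_params}.
#' @param grid a \code{grid_spec} (ignored in well-mixed mode).
#' @param t_eval output times in seconds, starting at 0, strictly
#'   increasing.
#' @param boundary a [boundary_conditions()] list.
#' @param well_mixed single-node mode without transport.
#' @param fixed_CW if non-NULL (well-mixed mode only), water is clamped to
#'   this concentration, mol cm^-3.
#' @param rtol relative tolerance of the integrator.
#' @param atol_scale absolute tolerances are \code{atol_scale} times a
#'   per-species magnitude (initial \eqn{\mu_1} for polymer species,
#'   \code{CW_surface} for water, initial \eqn{\mu_2} for \eqn{\mu_2}).
#' @return A \code{trajectory}: list with \code{times} (s), \code{states}
#'   (a \code{field_state} per output time), \code{device_Mn},
#'   \code{device_Mw}, \code{device_PD}, and \code{diagnostics} (clipped
#'   negative values, solver steps).
#' @export
#' @examples
#' p <- model_params(kd = 3.85e-5, Mn_ref = 406000)
#' st <- init_uniform(406000, 1.6, p, grid = 1)
#' tr <- integrate_film(st, p, t_eval = seq(0, 3e7, length.out = 5),
#'                      well_mixed = TRUE, fixed_CW = 0.0555)
#' tr$device_Mn
integrate_film <- function(init, params, grid = grid_spec(),
                           t_eval,
                           boundary = boundary_conditions(),
                           well_mixed = FALSE, fixed_CW = NULL,
                           rtol = 1e-6, atol_scale = 1e-9) {
  if (!is.numeric(t_eval) || length(t_eval) < 2L || t_eval[1L] != 0 ||
      any(diff(t_eval) <= 0))
    stop("'t_eval' must start at 0 and be strictly increasing",
         call. = FALSE)
  if (!is.null(fixed_CW) && !well_mixed)
    stop("'fixed_CW' is only meaningful in well-mixed mode", call. = FALSE)
  validate_field_state(init)
  m <- init$n_nodes
  if (well_mixed) {
    if (m != 1L) stop("well-mixed mode needs a single-node state",
                      call. = FALSE)
  } else {
    if (m != grid$n_nodes)
      stop("state and grid disagree on the number of nodes", call. = FALSE)
  }

  st0 <- init
  if (well_mixed && !is.null(fixed_CW)) st0$CW[] <- fixed_CW
  if (!well_mixed) {
    # pin Dirichlet surface values before integrating
    if (boundary$water == "dirichlet") st0$CW[m] <- params$CW_surface
    if (boundary$species == "sink") { st0$CM[m] <- 0; st0$C[m, ] <- 0 }
  }
  y0 <- .pack_state(st0)

  mu1s <- max(st0$mu1, 1e-12)
  mu2s <- max(st0$mu2, mu1s)
  scales <- c(params$CW_surface, rep(mu1s, 10L), mu1s, mu2s)
  atol <- rep(scales * atol_scale, times = m)

  clamp_W <- well_mixed && !is.null(fixed_CW)
  func <- function(t, y, p) {
    d <- .rhs_field(.unpack_state(y), params, grid, boundary,
                    diffusion = !well_mixed)
    if (clamp_W) d$CW[] <- 0
    list(.pack_state(d))
  }

  out <- if (m >= 3L) {
    deSolve::lsoda(y0, t_eval, func, parms = NULL, rtol = rtol, atol = atol,
                   jactype = "bandint", bandup = 2L * .NSPEC,
                   banddown = 2L * .NSPEC, maxsteps = 100000L)
  } else {
    deSolve::lsoda(y0, t_eval, func, parms = NULL, rtol = rtol, atol = atol,
                   maxsteps = 100000L)
  }
  if (nrow(out) < length(t_eval)) {
    stop(sprintf(
      "integration failed at t = %.6g s (requested horizon %.6g s)",
      out[nrow(out), 1L], t_eval[length(t_eval)]), call. = FALSE)
  }

  ymat <- out[, -1L, drop = FALSE]
  n_below <- sum(ymat < -rep(atol, each = nrow(ymat)))
  if (n_below > 0L)
    message(n_below, " state value(s) below -atol were clipped to zero")
  ymat[ymat < 0] <- 0

  nt <- length(t_eval)
  states <- vector("list", nt)
  Mn <- Mw <- PD <- numeric(nt)
  x <- if (well_mixed) 0 else grid$x
  for (i in seq_len(nt)) {
    sti <- .unpack_state(ymat[i, ])
    states[[i]] <- field_state(sti$CW, sti$CM, sti$C,
                               sti$mu0, sti$mu1, sti$mu2)
    if (well_mixed) {
      av <- averages(sti$mu0, sti$mu1, sti$mu2, params$Mmon)
    } else {
      av <- averages(.trapz(x, sti$mu0), .trapz(x, sti$mu1),
                     .trapz(x, sti$mu2), params$Mmon)
    }
    Mn[i] <- av$Mn; Mw[i] <- av$Mw; PD[i] <- av$PD
  }
  structure(list(times = t_eval, states = states,
                 device_Mn = Mn, device_Mw = Mw, device_PD = PD,
                 diagnostics = list(clipped = n_below,
                                    steps = attr(out, "istate")[3L]),
                 params = params,
                 well_mixed = well_mixed),
            class = "trajectory")
}

.trapz <- function(x, y) {
  if (length(x) == 1L) return(y)
  sum(diff(x) * (y[-1L] + y[-length(y)])) / 2
}

#' @export
print.trajectory <- function(x, ...) {
  nt <- length(x$times)
  cat(sprintf("trajectory: %d output times over %.4g days (%s)\n",
              nt, x$times[nt] / 86400,
              if (x$well_mixed) "well-mixed" else
                sprintf("%d nodes", x$states[[1L]]$n_nodes)))
  cat(sprintf("  device Mn: %.6g -> %.6g g mol^-1\n",
              x$device_Mn[1L], x$device_Mn[nt]))
  cat(sprintf("  device PD: %.4g -> %.4g\n",
              x$device_PD[1L], x$device_PD[nt]))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_days = x$times / 86400,
             Mn_g_mol = x$device_Mn,
             Mw_g_mol = x$device_Mw,
             PD = x$device_PD)
}
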