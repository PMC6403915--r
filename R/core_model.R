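#' Field state of the degradation model
#'
#' The full state of the reaction-diffusion model at each grid node: water and
#' monomer concentrations, oligomer concentrations for chain lengths 2 to 9
#' (the lengths assumed mobile in the polymer matrix), and the first three
#' statistical moments of the chain-length distribution,
#' \eqn{\mu_j = \sum_{n \ge 1} n^j C_n} (mol cm^-3). The monomer is counted
#' inside the moments (the sum starts at n = 1).
#'
#' @param CW water concentration per node, mol cm^-3.
#' @param CM monomer concentration per node, mol cm^-3.
#' @param C numeric matrix (nodes x 8) of oligomer concentrations, columns
#'   \code{C2} to \code{C9}, mol cm^-3.
#' @param mu0,mu1,mu2 statistical moments per node, mol cm^-3.
#' @return An object of class \code{field_state}.
#' @export
field_state <- function(CW, CM, C, mu0, mu1, mu2) {
  m <- length(CW)
  C <- as.matrix(C)
  if (length(CM) != m || nrow(C) != m || ncol(C) != 8L ||
      length(mu0) != m || length(mu1) != m || length(mu2) != m)
    stop("inconsistent field lengths in field_state", call. = FALSE)
  colnames(C) <- paste0("C", 2:9)
  st <- structure(list(CW = as.numeric(CW), CM = as.numeric(CM), C = C,
                       mu0 = as.numeric(mu0), mu1 = as.numeric(mu1),
                       mu2 = as.numeric(mu2), n_nodes = m),
                  class = "field_state")
  validate_field_state(st)
  st
}

#' Validate the physical invariants of a field state
#'
#' Checks non-negativity of all concentrations, that chains are at least one
#' unit long (\eqn{\mu_1 \ge \mu_0}), the Cauchy-Schwarz moment inequality
#' \eqn{\mu_2 \mu_0 \ge \mu_1^2} (polydispersity >= 1), and that no single
#' resolved species exceeds the total chain concentration \eqn{\mu_0}.
#'
#' @param st a \code{field_state}.
#' @param tol absolute slack allowed on each inequality (integrator noise).
#' @return \code{st}, invisibly; errors on violation.
#' @export
validate_field_state <- function(st, tol = 1e-12) {
  neg <- min(st$CW, st$CM, st$C, st$mu0, st$mu1, st$mu2)
  if (neg < -tol)
    stop("negative concentration in field_state (min = ", format(neg), ")",
         call. = FALSE)
  if (any(st$mu1 - st$mu0 < -tol * pmax(1, st$mu1)))
    stop("mu1 < mu0: mean chain length below one repeating unit",
         call. = FALSE)
  if (any(st$mu2 * st$mu0 - st$mu1^2 < -1e-8 * pmax(1e-300, st$mu1^2)))
    stop("mu2*mu0 < mu1^2: polydispersity below 1", call. = FALSE)
  resolved <- pmax(st$CM, apply(st$C, 1L, max))
  if (any(resolved - st$mu0 > tol + 1e-8 * st$mu0))
    stop("a resolved species exceeds the chain concentration mu0",
         call. = FALSE)
  invisible(st)
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("field_state: %d node(s)\n", x$n_nodes))
  cat(sprintf("  CW  [%.3g, %.3g]  CM  [%.3g, %.3g] mol cm^-3\n",
              min(x$CW), max(x$CW), min(x$CM), max(x$CM)))
  cat(sprintf("  mu0 [%.3g, %.3g]  mu1 [%.3g, %.3g]  mu2 [%.3g, %.3g]\n",
              min(x$mu0), max(x$mu0), min(x$mu1), max(x$mu1),
              min(x$mu2), max(x$mu2)))
  invisible(x)
}

#' Degradation-enhanced effective diffusivity
#'
#' Chain scission opens wider diffusive paths, so each species' diffusivity
#' grows as the local number-average molecular weight falls:
#' \deqn{D = D^0 \exp\!\left[2.5\,\bigl(1 - M_n/M_n^{ref}\bigr)^{0.5}\right]}
#' bounded between \eqn{D^0} (pristine) and \eqn{D^0 e^{2.5}} (fully
#' degraded). Local molecular weights transiently above the reference are
#' clamped to the reference.
#'
#' @param D0 pristine diffusivity, cm^2 s^-1 (> 0).
#' @param Mn_local local number-average molecular weight, g mol^-1.
#' @param Mn_ref number-average molecular weight before degradation onset.
#' @return effective diffusivity, cm^2 s^-1 (vectorised over
#'   \code{Mn_local}).
#' @export
#' @examples
#' effective_diffusivity(1e-10, 406000, 406000)  # pristine: 1e-10
#' effective_diffusivity(1e-10, 0, 406000)       # fully degraded: e^2.5 x
effective_diffusivity <- function(D0, Mn_local, Mn_ref) {
  if (!is.numeric(D0) || any(D0 <= 0) || !all(is.finite(D0)))
    stop("'D0' must be positive and finite", call. = FALSE)
  if (!is.numeric(Mn_ref) || any(Mn_ref <= 0) || !all(is.finite(Mn_ref)))
    stop("'Mn_ref' must be positive and finite", call. = FALSE)
  frac <- pmin(pmax(Mn_local / Mn_ref, 0), 1)
  D0 * exp(2.5 * sqrt(1 - frac))
}

#' Reaction source terms of the population-balance model
#'
#' Returns the local (non-transport) rates of change produced by random
#' hydrolytic chain scission with autocatalysis. Writing \eqn{k = k_d C_W
#' \mu_0} for the per-bond scission frequency scale:
#' \itemize{
#'   \item monomer: \eqn{+2 k_d C_W (\mu_0 - C_M) \mu_0} (each scission of
#'     a chain adjacent to its end releases a monomer from either end);
#'   \item water: \eqn{-k_d C_W (\mu_1 - \mu_0) \mu_0} (one water consumed
#'     per bond broken; \eqn{\mu_1 - \mu_0} is the bond concentration);
#'   \item oligomer of length n (2..9):
#'     \eqn{+2 k_d C_W (\mu_0 - \sum_{j \le n} C_j) \mu_0
#'          - (n-1) k_d C_W C_n \mu_0};
#'   \item \eqn{\mu_0}: \eqn{+k_d C_W (\mu_1 - \mu_0) \mu_0} (each scission
#'     creates one chain);
#'   \item \eqn{\mu_1}: 0 (scission conserves repeating units);
#'   \item \eqn{\mu_2}: \eqn{+k_d C_W (\mu_0/3)\,(\mu_1 - 2\mu_2^2/\mu_1 +
#'     \mu_2 \mu_1 / \mu_0)}, using the moment closure
#'     \eqn{\mu_3 \approx 2\mu_2^2/\mu_1 - \mu_2\mu_1/\mu_0}, which is exact
#'     for monodisperse states.
#' }
#' Nodes that are empty or fully degraded (\eqn{\mu_0 = 0} or
#' \eqn{\mu_1 = 0}) yield a zero second-moment source rather than an error.
#'
#' @param state a \code{field_state} (any number of nodes) or a list with
#'   components \code{CW}, \code{CM}, \code{C} (nodes x 8), \code{mu0},
#'   \code{mu1}, \code{mu2}.
#' @param params a \code{model_params}.
#' @return list with components \code{CW}, \code{CM}, \code{C},
#'   \code{mu0}, \code{mu1}, \code{mu2}: source terms, mol cm^-3 s^-1.
#' @export
reaction_sources <- function(state, params) {
  kd <- params$kd
  CW <- state$CW; CM <- state$CM; C <- state$C
  mu0 <- state$mu0; mu1 <- state$mu1; mu2 <- state$mu2
  a <- kd * CW * mu0                      # common third-order factor
  src_CM <- 2 * a * (mu0 - CM)
  src_CW <- -a * (mu1 - mu0)
  src_mu0 <- a * (mu1 - mu0)
  src_mu1 <- numeric(length(mu0))
  ok <- mu0 > 0 & mu1 > 0
  src_mu2 <- numeric(length(mu0))
  if (any(ok)) {
    src_mu2[ok] <- kd * CW[ok] * (mu0[ok] / 3) *
      (mu1[ok] - 2 * mu2[ok]^2 / mu1[ok] + mu2[ok] * mu1[ok] / mu0[ok])
  }
  # cumulative concentration of chains no longer than n, n = 1..9
  src_C <- matrix(0, nrow = length(mu0), ncol = 8L,
                  dimnames = list(NULL, paste0("C", 2:9)))
  cum <- CM
  for (j in 1:8) {
    Cn <- C[, j]
    cum <- cum + Cn
    n <- j + 1L
    src_C[, j] <- 2 * a * (mu0 - cum) - (n - 1L) * a * Cn
  }
  list(CW = src_CW, CM = src_CM, C = src_C,
       mu0 = src_mu0, mu1 = src_mu1, mu2 = src_mu2)
}

#' Average molecular weights and polydispersity from moments
#'
#' \deqn{M_n = (\mu_1/\mu_0)\,M_{mon}, \quad M_w = (\mu_2/\mu_1)\,M_{mon},
#'       \quad PD = \mu_2 \mu_0 / \mu_1^2.}
#' The identity \eqn{M_w = PD \cdot M_n} holds exactly.
#'
#' @param mu0,mu1,mu2 statistical moments, mol cm^-3 (vectorised).
#' @param Mmon repeating-unit molar mass, g mol^-1.
#' @return list with numeric components \code{Mn}, \code{Mw}, \code{PD}.
#' @export
#' @examples
#' # monodisperse chains of length 100:
#' averages(1e-6, 1e-4, 1e-2, Mmon = 90.08)
averages <- function(mu0, mu1, mu2, Mmon) {
  if (any(mu0 <= 0) || any(mu1 <= 0))
    stop("averages undefined: mu0 and mu1 must be strictly positive",
         call. = FALSE)
  list(Mn = mu1 / mu0 * Mmon,
       Mw = mu2 / mu1 * Mmon,
       PD = mu2 * mu0 / mu1^2)
}
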