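#' Construct a uniform initial state from macroscopic polymer properties
#'
#' Inverts the moment-to-averages map: given the initial number-average
#' molecular weight and polydispersity of a dry film, every node receives
#' \deqn{\mu_1 = \rho_{pol}/M_{mon}, \quad \mu_0 = \rho_{pol}/M_{n,0}, \quad
#'       \mu_2 = PD_0\,\mu_1^2/\mu_0,}
#' so that [averages()] applied to the result returns
#' \eqn{(M_{n,0},\; PD_0 M_{n,0},\; PD_0)} to machine precision. Water,
#' monomer and oligomer concentrations start at zero: the film is dry and
#' the initial mass fraction of short species in a high-molecular-weight
#' polymer is negligible. A pre-saturated start (water everywhere at a given
#' concentration) is available through \code{CW0}.
#'
#' @param Mn0 initial number-average molecular weight, g mol^-1
#'   (>= \code{params$Mmon}).
#' @param PD0 initial polydispersity (>= 1).
#' @param params a \code{model_params}.
#' @param grid a \code{grid_spec}, or an integer taken as a node count with
#'   the default half-thickness; \code{grid = 1} gives the single-node state
#'   used by the well-mixed model.
#' @param CW0 initial water concentration at every node, mol cm^-3
#'   (default 0, dry polymer).
#' @return A \code{field_state} with one row per grid node.
#' @export
#' @examples
#' p <- model_params()
#' st <- init_uniform(406000, 1.60, p, grid = 1)
#' averages(st$mu0, st$mu1, st$mu2, p$Mmon)   # recovers 406000, 1.60
init_uniform <- function(Mn0, PD0, params, grid = grid_spec(), CW0 = 0) {
  if (!is.numeric(Mn0) || length(Mn0) != 1L || !is.finite(Mn0) ||
      Mn0 < params$Mmon)
    stop("'Mn0' must be a single number >= Mmon (at least one repeating unit)",
         call. = FALSE)
  if (!is.numeric(PD0) || length(PD0) != 1L || !is.finite(PD0) || PD0 < 1)
    stop("'PD0' must be a single number >= 1", call. = FALSE)
  if (CW0 < 0) stop("'CW0' must be non-negative", call. = FALSE)
  m <- if (inherits(grid, "grid_spec")) grid$n_nodes else as.integer(grid)
  if (is.na(m) || m < 1L) stop("invalid grid", call. = FALSE)
  mu1 <- params$rho_pol / params$Mmon
  mu0 <- params$rho_pol / Mn0
  mu2 <- PD0 * mu1^2 / mu0
  field_state(CW = rep(CW0, m), CM = rep(0, m),
              C = matrix(0, m, 8L),
              mu0 = rep(mu0, m), mu1 = rep(mu1, m), mu2 = rep(mu2, m))
}
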