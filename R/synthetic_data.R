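#' Reference degradation study design
#'
#' The four-dose electron-beam study the package's fixtures emulate: initial
#' number-average molecular weight and polydispersity of the irradiated
#' polylactide films per radiation dose, and the degradation kinetic
#' constant fitted for each.
#'
#' @return data.frame with columns \code{dose_Mrad}, \code{Mn0} (g mol^-1),
#'   \code{PD0}, \code{kd} (cm^6 mol^-2 s^-1).
#' @export
#' @examples
#' dose_table()
dose_table <- function() {
  data.frame(dose_Mrad = c(0, 5, 10, 20),
             Mn0 = c(406000, 64700, 43200, 23100),
             PD0 = c(1.60, 1.68, 1.73, 1.76),
             kd = c(3.85e-5, 1.27e-4, 1.47e-4, 1.21e-4))
}

#' Time horizon for a target fractional Mn decline (well-mixed, fixed water)
#'
#' With water held fixed, the chain-concentration balance
#' \eqn{d\mu_0/dt = k_d C_W (\mu_1 - \mu_0)\mu_0} is logistic and
#' \eqn{M_n(t)/M_n(0) = \mu_0(0)/\mu_0(t)}, giving a closed-form time at
#' which Mn reaches a fraction of its initial value:
#' \deqn{t = \frac{1}{k_d C_W \mu_1}
#'       \ln\frac{\mu_0^{tgt}(\mu_1 - \mu_0^0)}
#'               {\mu_0^0(\mu_1 - \mu_0^{tgt})},\qquad
#'       \mu_0^{tgt} = \mu_0^0 / frac.}
#' Used to design measurement schedules with comparable fractional decline
#' across doses.
#'
#' @param kd degradation kinetic constant, cm^6 mol^-2 s^-1.
#' @param Mn0 initial number-average molecular weight, g mol^-1.
#' @param frac target \eqn{M_n/M_{n,0}} in (0, 1).
#' @param params a \code{model_params}.
#' @param CW fixed water concentration, mol cm^-3.
#' @return time in days.
#' @export
mn_decline_horizon <- function(kd, Mn0, frac, params = model_params(),
                               CW = params$CW_surface) {
  if (frac <= 0 || frac >= 1) stop("'frac' must be in (0, 1)", call. = FALSE)
  mu1 <- params$rho_pol / params$Mmon
  mu00 <- params$rho_pol / Mn0
  mu0t <- mu00 / frac
  if (mu0t >= mu1)
    stop("target decline exceeds full depolymerisation", call. = FALSE)
  t_s <- log(mu0t * (mu1 - mu00) / (mu00 * (mu1 - mu0t))) / (kd * CW * mu1)
  t_s / 86400
}

#' Generate a synthetic molecular-weight decay dataset
#'
#' Runs the well-mixed forward model (water fixed at the surface
#' concentration) and multiplies each Mn value by an independent lognormal
#' factor with unit mean and coefficient of variation \code{noise_cv},
#' emulating the roughly constant relative error of GPC molecular-weight
#' determinations. A fixed seed makes the dataset bit-reproducible.
#'
#' @param kd true degradation kinetic constant, cm^6 mol^-2 s^-1.
#' @param Mn0,PD0 initial molecular weight (g mol^-1) and polydispersity.
#' @param times_days measurement times, days.
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise (0 = noiseless).
#' @param seed RNG seed.
#' @param params a \code{model_params}.
#' @param dose_label label attached to the dataset.
#' @param fixed_CW water concentration of the forward model, mol cm^-3.
#' @return a \code{degradation_dataset} with metadata \code{kd_true},
#'   \code{seed}, \code{noise_cv}.
#' @export
#' @examples
#' d <- generate_dataset(3.85e-5, 406000, 1.6,
#'                       times_days = seq(0, 372, length.out = 12),
#'                       noise_cv = 0.03, seed = 42)
#' d
generate_dataset <- function(kd, Mn0, PD0, times_days, noise_cv = 0.03,
                             seed = 1L, params = model_params(),
                             dose_label = "", fixed_CW = params$CW_surface) {
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  Mn_true <- .forward_mn(kd, Mn0, PD0, times_days, params,
                         well_mixed = TRUE, fixed_CW = fixed_CW)
  set.seed(seed)
  sdlog <- sqrt(log1p(noise_cv^2))
  factors <- stats::rlnorm(length(Mn_true), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog)
  degradation_dataset(times_days, Mn_true * factors,
                      dose_label = dose_label, Mn0 = Mn0, PD0 = PD0,
                      metadata = list(kd_true = kd, seed = seed,
                                      noise_cv = noise_cv,
                                      fixed_CW = fixed_CW))
}

#' Write the four-dose fixture suite
#'
#' Generates one CSV dataset per radiation dose (0, 5, 10, 20 Mrad) from the
#' reference study design of [dose_table()]: 12 time points from 0 to the
#' horizon at which Mn reaches 40% of its initial value (rounded to whole
#' days), 3% multiplicative measurement noise, seed \code{851 + dose} for
#' dose d Mrad. Files are named \code{dose<d>.csv}; regeneration with the
#' same arguments is byte-identical.
#'
#' @param outdir writable directory.
#' @param noise_cv noise level passed to [generate_dataset()].
#' @param n_points measurements per dataset.
#' @param frac target fractional Mn decline defining each horizon.
#' @return invisibly, a named character vector of the files written.
#' @export
make_fixture_suite <- function(outdir, noise_cv = 0.03, n_points = 12L,
                               frac = 0.4) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  design <- dose_table()
  params <- model_params()
  files <- character(nrow(design))
  for (i in seq_len(nrow(design))) {
    dose <- design$dose_Mrad[i]
    horizon <- round(mn_decline_horizon(design$kd[i], design$Mn0[i], frac,
                                        params))
    times <- round(seq(0, horizon, length.out = n_points))
    d <- generate_dataset(design$kd[i], design$Mn0[i], design$PD0[i],
                          times, noise_cv = noise_cv,
                          seed = 851L + as.integer(dose), params = params,
                          dose_label = sprintf("%g Mrad", dose))
    path <- file.path(outdir, sprintf("dose%g.csv", dose))
    write_dataset(d, path)
    files[i] <- path
  }
  names(files) <- sprintf("%g Mrad", design$dose_Mrad)
  invisible(files)
}
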