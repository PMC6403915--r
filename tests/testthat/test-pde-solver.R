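test_that("uniform sealed state with kd = 0 has zero time derivative", {
  p <- ref_params(kd = 0)
  g <- grid_spec(n_nodes = 21L)
  st <- init_uniform(406000, 1.6, p, g, CW0 = 0.02)
  d <- assemble_rhs(st, p, g,
                    boundary = boundary_conditions("zeroflux", "zeroflux"))
  expect_equal(max(abs(unlist(d))), 0)
})

test_that("no water means no hydrolysis anywhere", {
  p <- ref_params()
  g <- grid_spec(n_nodes = 21L)
  st <- init_uniform(406000, 1.6, p, g, CW0 = 0)
  d <- assemble_rhs(st, p, g,
                    boundary = boundary_conditions("zeroflux", "zeroflux"))
  expect_equal(max(abs(unlist(d))), 0)
  # and the device Mn stays constant over a long sealed run
  tr <- integrate_film(st, p, g, t_eval = c(0, 1e7),
                       boundary = boundary_conditions("zeroflux",
                                                      "zeroflux"))
  expect_equal(tr$device_Mn[2], tr$device_Mn[1], tolerance = 1e-10)
})

test_that("with diffusion disabled the rhs equals the reaction sources", {
  p <- ref_params()
  set.seed(5)
  st <- random_state(1L)
  d <- assemble_rhs(st, p, grid_spec(), diffusion = FALSE)
  s <- reaction_sources(st, p)
  expect_identical(unlist(d), unlist(s))
})

test_that("sealed runs conserve the repeating-unit inventory", {
  p <- ref_params()
  g <- grid_spec(n_nodes = 51L)
  st <- init_uniform(406000, 1.6, p, g)
  # graded pre-saturation so transport is genuinely exercised
  st$CW <- p$CW_surface * seq(0.5, 1, length.out = g$n_nodes)
  tr <- integrate_film(st, p, g, t_eval = seq(0, 4e7, length.out = 9),
                       boundary = boundary_conditions("zeroflux",
                                                      "zeroflux"))
  int_mu1 <- vapply(tr$states, function(s) trapz(g$x, s$mu1), numeric(1))
  expect_lt(max(abs(int_mu1 / int_mu1[1] - 1)), 1e-3)
  # Mn falls substantially while mass is conserved
  expect_lt(tr$device_Mn[9] / tr$device_Mn[1], 0.5)
})

test_that("well-mixed fixed-water trajectory matches the logistic closed form", {
  # with CW fixed, d(mu0)/dt = kd CW (mu1 - mu0) mu0 is logistic:
  # mu0(t) = mu1 mu00 E / (mu1 - mu00 + mu00 E), E = exp(kd CW mu1 t)
  p <- ref_params(kd = 3.85e-5)
  CW <- 0.0555
  st <- init_uniform(406000, 1.6, p, grid = 1L)
  tt <- seq(0, 4e7, length.out = 9)
  tr <- integrate_film(st, p, t_eval = tt, well_mixed = TRUE,
                       fixed_CW = CW)
  mu1 <- st$mu1; mu00 <- st$mu0
  E <- exp(p$kd * CW * mu1 * tt)
  mu0_exact <- mu1 * mu00 * E / (mu1 - mu00 + mu00 * E)
  Mn_exact <- mu1 / mu0_exact * p$Mmon
  expect_equal(tr$device_Mn, Mn_exact, tolerance = 1e-5)
})

test_that("surface-sink runs give non-increasing Mn and PD >= 1 throughout", {
  p <- ref_params()
  g <- grid_spec(n_nodes = 31L)
  st <- init_uniform(406000, 1.6, p, g)
  tr <- integrate_film(st, p, g, t_eval = seq(0, 4e7, length.out = 9))
  expect_true(all(diff(tr$device_Mn) <= 0))
  expect_true(all(tr$device_PD >= 1 - 1e-6))
  for (s in tr$states) {
    PD_nodes <- s$mu2 * s$mu0 / s$mu1^2
    expect_true(all(PD_nodes >= 1 - 1e-6))
  }
})

test_that("device Mn is grid-converged at the default resolution", {
  p <- ref_params()
  tt <- seq(0, 4e7, length.out = 9)
  g51 <- grid_spec(n_nodes = 51L)
  g101 <- grid_spec(n_nodes = 101L)
  tr51 <- integrate_film(init_uniform(406000, 1.6, p, g51), p, g51, tt)
  tr101 <- integrate_film(init_uniform(406000, 1.6, p, g101), p, g101, tt)
  expect_lt(max(abs(tr51$device_Mn / tr101$device_Mn - 1)), 0.01)
})

test_that("trajectory input validation and export work", {
  p <- ref_params()
  st <- init_uniform(406000, 1.6, p, grid = 1L)
  expect_error(integrate_film(st, p, t_eval = c(1, 2), well_mixed = TRUE),
               "start at 0")
  expect_error(integrate_film(st, p, t_eval = c(0, 2, 2),
                              well_mixed = TRUE),
               "increasing")
  expect_error(integrate_film(st, p, t_eval = c(0, 1e6),
                              fixed_CW = 0.05),
               "well-mixed")
  tr <- integrate_film(st, p, t_eval = c(0, 1e7, 2e7), well_mixed = TRUE,
                       fixed_CW = 0.0555)
  df <- as.data.frame(tr)
  expect_named(df, c("time_days", "Mn_g_mol", "Mw_g_mol", "PD"))
  expect_equal(df$time_days, c(0, 1e7, 2e7) / 86400)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_equal(back$Mn_g_mol, tr$device_Mn, tolerance = 1e-9)
  expect_true(file.exists(paste0(path, ".config.txt")))
})
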