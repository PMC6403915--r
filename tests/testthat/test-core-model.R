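test_that("effective diffusivity follows the degradation-enhancement law", {
  # pristine polymer: exponent zero
  expect_identical(effective_diffusivity(1e-10, 406000, 406000), 1e-10)
  # fully degraded: D0 * e^2.5
  expect_equal(effective_diffusivity(1e-10, 0, 406000),
               1e-10 * exp(2.5), tolerance = 1e-12)
  # partial degradation, direct evaluation: exp(2.5 * sqrt(0.25))
  expect_equal(effective_diffusivity(1e-10, 0.75 * 406000, 406000),
               1e-10 * exp(1.25), tolerance = 1e-12)
  # monotone non-increasing in Mn_local, bounded in [D0, D0 e^2.5],
  # values above Mn_ref clamped
  Mn <- seq(-1e4, 5e5, length.out = 200)
  D <- effective_diffusivity(1e-10, Mn, 406000)
  expect_true(all(diff(D[order(Mn)]) <= 0))
  expect_true(all(D >= 1e-10 - 1e-25 & D <= 1e-10 * exp(2.5) + 1e-25))
  expect_identical(effective_diffusivity(1e-10, 5e5, 406000), 1e-10)
  expect_error(effective_diffusivity(-1e-10, 1e5, 4e5), "positive")
  expect_error(effective_diffusivity(1e-10, 1e5, 0), "positive")
})

test_that("reaction sources vanish on an all-monomer node", {
  c0 <- 1e-5
  st <- field_state(CW = 0.05, CM = c0, C = matrix(0, 1, 8),
                    mu0 = c0, mu1 = c0, mu2 = c0)
  src <- reaction_sources(st, ref_params(kd = 1e-4))
  expect_equal(unlist(src), rep(0, 13), ignore_attr = TRUE)
})

test_that("monomer source matches direct evaluation of the scission rate", {
  # 2 * kd * CW * (mu0 - CM) * mu0 = 2 * 1e-4 * 0.05 * 1e-5 * 1e-5 = 1e-15
  st <- field_state(CW = 0.05, CM = 0, C = matrix(0, 1, 8),
                    mu0 = 1e-5, mu1 = 2e-5, mu2 = 4e-5)
  src <- reaction_sources(st, ref_params(kd = 1e-4))
  expect_equal(src$CM, 1e-15, tolerance = 1e-12)
})

test_that("second-moment closure reproduces the exact monodisperse rate", {
  # monodisperse length n: closure mu3 = 2 mu2^2/mu1 - mu2 mu1/mu0 equals
  # n^3 mu0 exactly, so the mu2 source is -(kd CW mu0/3)(mu3 - mu1)
  kd <- 1e-4; CW <- 0.05
  for (n in c(2, 10, 100, 1000)) {
    c0 <- 1e-6
    mu0 <- c0; mu1 <- n * c0; mu2 <- n^2 * c0
    closure <- 2 * mu2^2 / mu1 - mu2 * mu1 / mu0
    expect_equal(closure, n^3 * c0, tolerance = 1e-12)
    st <- field_state(CW = CW, CM = 0, C = matrix(0, 1, 8),
                      mu0 = mu0, mu1 = mu1, mu2 = mu2)
    src <- reaction_sources(st, ref_params(kd = kd))
    exact <- -(kd * CW * mu0 / 3) * (n^3 * c0 - mu1)
    expect_equal(src$mu2, exact, tolerance = 1e-12)
  }
  # frozen value for the n = 100 case of the loop above
  st <- field_state(CW = 0.05, CM = 0, C = matrix(0, 1, 8),
                    mu0 = 1e-6, mu1 = 1e-4, mu2 = 1e-2)
  expect_equal(reaction_sources(st, ref_params(kd = 1e-4))$mu2,
               -1.66650e-12, tolerance = 1e-5)
})

test_that("sources are linear in kd and CW, with the stated sign structure", {
  set.seed(7)
  p1 <- ref_params(kd = 2e-5)
  p2 <- ref_params(kd = 6e-5)
  for (i in 1:20) {
    st <- random_state()
    s1 <- reaction_sources(st, p1)
    s2 <- reaction_sources(st, p2)
    expect_equal(unlist(s2), 3 * unlist(s1), tolerance = 1e-12)
    st3 <- st; st3$CW <- 2.5 * st$CW
    s3 <- reaction_sources(st3, p1)
    expect_equal(unlist(s3), 2.5 * unlist(s1), tolerance = 1e-12)
    # first moment has no reaction term; sign structure when mu1 > mu0
    expect_identical(s1$mu1, 0)
    expect_true(s1$CW <= 0)
    expect_true(s1$mu0 >= 0)
    expect_true(s1$CM >= 0)
  }
})

test_that("degenerate (empty) nodes give zero second-moment source", {
  st <- list(CW = 0.05, CM = 0, C = matrix(0, 1, 8),
             mu0 = 0, mu1 = 0, mu2 = 0)
  src <- reaction_sources(st, ref_params(kd = 1e-4))
  expect_identical(src$mu2, 0)
  expect_identical(src$mu0, 0)
})

test_that("averages map moments to Mn, Mw, PD with Mw = PD * Mn", {
  # monodisperse length n: Mn = Mw = n * Mmon, PD = 1
  av <- averages(1e-6, 1e-4, 1e-2, Mmon = 90.08)
  expect_equal(av$Mn, 100 * 90.08, tolerance = 1e-12)
  expect_equal(av$Mw, 100 * 90.08, tolerance = 1e-12)
  expect_equal(av$PD, 1, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    st <- random_state()
    av <- averages(st$mu0, st$mu1, st$mu2, 90.08)
    expect_equal(av$Mw, av$PD * av$Mn, tolerance = 1e-12)
    expect_true(av$PD >= 1)
    expect_true(av$Mw >= av$Mn)
  }
  expect_error(averages(0, 1e-4, 1e-2, 90.08), "positive")
  expect_error(averages(1e-6, 0, 1e-2, 90.08), "positive")
})

test_that("field_state validation rejects unphysical states", {
  expect_error(field_state(CW = -1e-3, CM = 0, C = matrix(0, 1, 8),
                           mu0 = 1e-6, mu1 = 1e-4, mu2 = 1e-2),
               "negative")
  expect_error(field_state(CW = 0, CM = 0, C = matrix(0, 1, 8),
                           mu0 = 2e-4, mu1 = 1e-4, mu2 = 1e-2),
               "mu1 < mu0")
  expect_error(field_state(CW = 0, CM = 0, C = matrix(0, 1, 8),
                           mu0 = 1e-6, mu1 = 1e-4, mu2 = 9e-3),
               "polydispersity")
  expect_error(field_state(CW = 0, CM = 2e-6, C = matrix(0, 1, 8),
                           mu0 = 1e-6, mu1 = 1e-4, mu2 = 1e-2),
               "exceeds")
})

test_that("model parameter validation enforces positivity", {
  expect_error(model_params(kd = -1), ">= 0")
  expect_error(model_params(rho_pol = 0), "positive")
  expect_error(model_params(Mn_ref = 10), "repeating unit")
  expect_silent(model_params(kd = 0))
})
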