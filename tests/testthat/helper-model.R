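# shared fixtures: reference parameter set and random valid field states

ref_params <- function(kd = 3.85e-5, Mn_ref = 406000) {
  model_params(kd = kd, Mn_ref = Mn_ref)
}

# random single/multi-node state satisfying all field_state invariants:
# mean chain length >= 10, PD in [1.05, 1.9], resolved species well below mu0
random_state <- function(m = 1L) {
  mu1 <- 10^stats::runif(m, -3, -1)
  nbar <- stats::runif(m, 10, 5000)
  mu0 <- mu1 / nbar
  PD <- stats::runif(m, 1.05, 1.9)
  mu2 <- PD * mu1^2 / mu0
  CM <- mu0 * stats::runif(m, 0, 0.2)
  C <- matrix(stats::runif(m * 8, 0, 0.05), m, 8) * mu0
  field_state(CW = stats::runif(m, 0, 0.0555), CM = CM, C = C,
              mu0 = mu0, mu1 = mu1, mu2 = mu2)
}

# in-test trapezoid rule, independent of the package's internals
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2
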