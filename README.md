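# polyscission

Population-balance modelling of hydrolytic chain scission in bioresorbable
polyester films, and least-squares estimation of the degradation kinetic
constant from molecular-weight decay series.

Bioresorbable implants made of polylactide-family polyesters lose
molecular weight by random, water-driven, autocatalytic hydrolysis of
ester bonds. Quantifying *how fast* — one kinetic constant per material
and treatment — is what lets device developers compare, say, an
electron-beam-sterilised film against a pristine one. This package is for
polymer and biomaterials engineers who have GPC time series of
number-average molecular weight Mn(t) and want a mechanistic rate
constant, not an empirical half-life.

## The model

Instead of one balance per chain length (~10^5 equations), the
chain-length distribution is summarised by its statistical moments
μ_j = Σ_n n^j C_n. The model couples reaction and diffusion over the film
half-thickness for water, monomer, mobile oligomers (lengths 2–9) and the
moments μ0, μ1, μ2:

* scission rate per bond: k_d · C_W · μ0 (third-order kinetics; the μ0
  factor is autocatalysis by carboxylic chain ends),
* μ0 grows by one chain per scission, μ1 (repeating units) is conserved,
  μ2 closes with μ3 ≈ 2μ2²/μ1 − μ2μ1/μ0 (exact for monodisperse states),
* diffusivities grow with degradation:
  D = D⁰·exp[2.5·(1 − Mn/Mn⁰)^0.5],
* averages: Mn = (μ1/μ0)·Mmon, Mw = (μ2/μ1)·Mmon, PD = μ2μ0/μ1².

The PDE system is solved by the method of lines (centred finite
differences, stiff `deSolve` integration). Fitting minimises relative
Mn residuals over log10(k_d) with a well-mixed, water-saturated forward
model (a 55 µm film saturates in hours but degrades over months). A
chain-length-resolved population-balance oracle — no moment closure —
validates the moment equations, and a synthetic-data generator produces
degradation datasets with forward-model decay plus 3% lognormal
measurement noise.

## Worked example

Fit the bundled synthetic four-dose study (generator output emulating an
electron-beam irradiation series; seeds documented in
`make_fixture_suite()`):

```r
library(polyscission)
p <- model_params()

d <- read_dataset(system.file("extdata", "synthetic-dose0.csv",
                              package = "polyscission"),
                  dose_label = "0 Mrad")
d
#> degradation_dataset '0 Mrad': 12 points over 373 days, Mn 427478 -> 152711

fit_kd(d, p)
#> fit_result '0 Mrad': kd = 4.17e-05 cm^6 mol^-2 s^-1
#>   rms relative residual 0.0319, 8 iterations, converged

fits <- lapply(c(0, 5, 10, 20), function(dose) {
  path <- system.file("extdata", sprintf("synthetic-dose%d.csv", dose),
                      package = "polyscission")
  fit_kd(read_dataset(path, dose_label = sprintf("%d Mrad", dose)), p)
})
nrm <- normalize_constants(fits, "0 Mrad")
round(nrm$ratios, 2)
#>  0 Mrad  5 Mrad 10 Mrad 20 Mrad
#>    1.00    3.03    3.51    2.92
round(nrm$mean_ratio, 2)
#> [1] 3.15
```

The fitted constant is the hydrolysis rate constant k_d in
cm^6 mol^-2 s^-1; 4.17e-05 recovers the generator's true 3.85e-05 within
the 3% measurement noise. The normalised ratios say the irradiated
samples hydrolyse about 3–3.5 times faster than the pristine polymer,
with no trend in dose — the acceleration comes from irradiation as such,
not its magnitude.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/polyscission generate --dose 5 --seed 3
Rscript inst/cli/polyscission fit --data dose5.csv
Rscript inst/cli/polyscission simulate --days 365 --out traj.csv
Rscript inst/cli/polyscission oracle-check
```

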