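Package: polyscission
Title: Population-Balance Modelling of Hydrolytic Polymer Chain Scission
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Moment-based population-balance reaction-diffusion modelling of
    autocatalytic hydrolytic degradation of bioresorbable polyesters in thin
    films. Tracks water, monomer and short-oligomer transport together with
    the first three statistical moments of the chain-length distribution,
    computes number- and weight-average molecular weights and polydispersity,
    and estimates the degradation kinetic constant from molecular-weight
    decay time series by nonlinear least squares. Includes a chain-length
    resolved population-balance oracle for validating the moment closure, a
    synthetic degradation-dataset generator, CSV input/output and a small
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
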