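Package: erpfield
Title: Probabilistic Calibration of Atrial Electrophysiology Parameter
    Fields from Refractory Period Measurements
Version: 0.1.0
Authors@R:
    person("ERP Field", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for calibrating spatially varying electrophysiology
    parameters on atrial surface meshes from sparse, interval-censored
    measurements of the effective refractory period (ERP).  Includes a 1D
    modified Mitchell-Schaeffer cable simulator with S1S2 and S1S2S3
    pacing protocols, reduced-rank Gaussian process priors built from
    Laplace-Beltrami eigenfunctions of a triangle mesh, cubic polynomial
    surrogate functions mapping local parameters to ERP, a smoothed
    top-hat likelihood for interval observations, Hamiltonian Monte Carlo
    over the latent field hyperparameters, and a synthetic-experiment
    module for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    mgcv,
    igraph,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
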