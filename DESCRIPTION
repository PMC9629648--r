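Package: hopfwb
Title: Whole-Brain Hopf Model Simulation, Fitting and In Silico Perturbation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Coupled Stuart-Landau (Hopf) oscillator models of whole-brain
    resting-state BOLD dynamics. Builds exponential-distance-rule (EDR) and
    EDR-plus-long-range coupling matrices from parcellation geometry and
    structural connectivity, integrates the coupled stochastic system with
    optional periodic forcing, and computes the observables used to fit such
    models: local and global Kuramoto order parameters, amplitude turbulence,
    metastability, and functional-connectivity comparison metrics. Provides
    exhaustive grid fitting of the global coupling and shear parameters,
    regime comparison with surrogate models, strength-dependent in silico
    perturbation protocols (susceptibility, information capability, and a
    BOLD-adapted perturbational complexity index based on normalized
    Lempel-Ziv complexity), resting-state-network modulation analyses, and a
    synthetic-data generator with known ground truth for validating the whole
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
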