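Package: vegftraffic
Title: Ligand-Modified Trafficking and Activation of VEGF Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Mechanistic compartmental model of VEGFR1, VEGFR2 and
    Neuropilin-1 synthesis, trafficking, ligand binding and dimerization in
    human endothelial cells. Enumerates the rule-based reaction network of
    receptor-ligand complexes, integrates the resulting stiff mass-action
    system through pre-simulation to steady state and event-driven ligand
    or knockdown perturbations, and implements the downstream analyses:
    localized receptor and active-complex observables, Scatchard model
    comparison, decoy-effect and ligand-competition quantification, local
    sensitivity analysis, the ligand-induced internalization multiplier
    scan, and a synthetic western-blot data generator for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    jsonlite,
    ggplot2,
    generics,
    rlang,
    stats,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
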