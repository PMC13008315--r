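Package: bbbivive
Title: In Vitro to In Vivo Extrapolation of Blood-Brain Barrier Transport
Version: 0.1.0
Authors@R:
    person("BBB", "IVIVE Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for bidirectional Transwell permeability
    assays on in vitro blood-brain-barrier models and extrapolation of the
    results to in vivo brain exposure. Reconstructs cumulative transported
    mass from receiver-chamber samples taken with buffer replacement,
    estimates apparent permeability coefficients (Papp) with replicate
    aggregation and quality-control flags, computes efflux ratios with
    censoring-aware bound propagation, classifies permeability rate and
    directional transport, and predicts acute brain-uptake kinetics
    (permeability-surface-area clearance, uptake rate constant, half-life)
    and chronic steady-state brain concentrations from toxicokinetic serum
    parameters. Includes a two-compartment Transwell simulator for
    generating synthetic assay data with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
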