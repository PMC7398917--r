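Package: cpmgrd
Title: CPMG Relaxation Dispersion Analysis of Two-State Conformational Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of 15N Carr-Purcell-Meiboom-Gill (CPMG)
    relaxation dispersion experiments on proteins undergoing two-state
    conformational exchange. Converts peak intensities to effective
    transverse relaxation rates with signal-to-noise error propagation,
    estimates the exchange-free baseline, classifies residues into
    no-exchange, fast and dispersive regimes, and fits dispersion profiles
    with a numerical Bloch-McConnell two-state model at four levels
    (per residue, global per temperature, global across temperatures,
    and thermodynamically constrained via van't Hoff and Eyring laws).
    Also provides R2/R1 exchange flagging and rotational-correlation-time
    estimation from rigid-rotor 15N relaxation, chemical-shift-perturbation
    mapping with significance thresholds, amide temperature coefficients,
    and a synthetic-data generator that emulates the full acquisition
    design so every stage is testable without experimental downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
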