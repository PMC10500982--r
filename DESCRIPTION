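Package: saisolv
Title: Serial-Atom-Insertion Absolute Solvation Free Energies on Toy Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, self-verifying implementation of the
    serial-atom-insertion (SAI) annihilation workflow for absolute solvation
    free energies (ASFEs): generation of per-atom charge/Lennard-Jones
    annihilation schedules, Metropolis Monte Carlo sampling of toy
    solute-water systems under CHARMM-style cutoff treatments, free energy
    estimation by the multistate Bennett acceptance ratio (MBAR) and by
    spline-integrated thermodynamic integration over a soft-core reference
    path, the analytic and a-posteriori Lennard-Jones long-range correction,
    and the benchmark statistics layer (RMSE/MAE/correlations with bootstrap
    confidence intervals, deviation counts, per-group and per-size summaries)
    used to compare computed and experimental solvation free energies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
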