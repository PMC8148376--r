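Package: phosflex
Title: Charge-Driven Conformational Response of Intrinsically Disordered
    Proteins to Multisite Phosphorylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how multisite phosphorylation reshapes the
    conformational ensembles of intrinsically disordered proteins (IDPs).
    Computes sequence charge descriptors (net charge, net charge per
    residue, charged fraction, sequence Coulomb force/potential) from
    phosphosite-annotated sequences; samples coarse-grained bead-chain
    ensembles by Metropolis Monte Carlo under a screened Debye-Hueckel
    electrostatic potential with tunable ionic strength; measures
    radius-of-gyration statistics with block-averaged errors and
    random-coil normalization; forward-calculates small-angle X-ray
    scattering (SAXS) curves by the Debye formula with an optional
    hydration-contrast shell, with Guinier and extended-Guinier fitting
    and chi-square curve comparison; counts salt bridges and quantifies
    binding-site shielding from solvent-accessible surface area; and fits
    the V-shape correlation of normalized radius of gyration with net
    charge per residue.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
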