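Package: cutoffmd
Title: Cutoff-Scheme Artifacts in Periodic Molecular Dynamics at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A minimal periodic molecular dynamics engine for studying how
    nonbonded cutoff and pairlist schemes shape simulation observables.
    Implements reaction-field electrostatics with atomistic, charge-group and
    solute-atomistic cutoff rules, single- and twin-range pairlists, leapfrog
    integration with SHAKE constraints and weak-coupling temperature and
    pressure baths.  Ships seeded builders for rigid three-site water boxes and
    toy charge-grouped solutes, a one-dimensional two-diatomic probe of cutoff
    energies and forces, solvent-structure diagnostics (radial distribution and
    dipole orientation correlation functions), per-bath temperature monitoring,
    and cross-scheme re-evaluation of stored trajectories with solute/solvent
    energy decomposition.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
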