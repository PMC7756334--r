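# cutoffmd

Nonbonded cutoff schemes are bookkeeping, but they leave fingerprints on the
physics.  `cutoffmd` is a small, self-contained periodic molecular dynamics
engine for R built to expose those fingerprints: it implements
reaction-field electrostatics with interchangeable cutoff rules — atomistic
(AT), charge-group-based with centre-of-geometry or designated-atom centres
(CG(cog), CG(OW)), and the mixed solute-atomistic rule (SA) — on single- and
twin-range pairlists, together with the diagnostics that make the resulting
artifacts visible: a one-dimensional two-diatomic probe of energies and
forces at the cutoff, solvent-structure observables (O–O radial distribution
function, dipole–dipole orientation correlation), per-bath temperature
monitoring, and cross-scheme re-evaluation of stored trajectories.

It is aimed at people teaching, reviewing or stress-testing simulation
methodology who want a transparent desk-scale testbed rather than a
production MD code.

## The model in brief

Electrostatics between charges $q_i, q_j$ use the reaction-field pair term

$$V^{el}_{ij} = \frac{q_i q_j}{4\pi\varepsilon_0}
 \left[\frac{1}{r_{ij}} - \frac{\tfrac12 C_{rf} r_{ij}^2}{R_{rf}^3}
 - \frac{1 - \tfrac12 C_{rf}}{R_{rf}}\right],
 \qquad C_{rf} = \frac{2(\varepsilon_{rf}-1)}{2\varepsilon_{rf}+1},$$

which vanishes exactly at the cutoff $R_{rf}$.  A cutoff *scheme* decides
which pairs enter the sum: per atom pair (AT) or per charge-group centre
pair, in which case all atoms of two in-range groups interact at their atomic
distances.  The twin-range pairlist evaluates short-range pairs every step
and freezes intermediate-range forces between list updates.  Dynamics are
2 fs leapfrog with SHAKE-rigid molecules (SPC water), separate solute and
solvent weak-coupling baths, and an optional weak-coupling barostat.  The
methods vignette (`vignettes/cutoff-schemes.Rmd`) derives every convention.

## A worked example

Reaction-field basics and the probe's group-scheme discontinuity:

```r
library(cutoffmd)
p <- rf_params(eps_rf = 61, r_rf = 1.4)
rf_constant(61)                 # 0.9756098  (= 120/123)
rf_pair_energy(1, 1, 0.7, p)    # 135.5468 kJ/mol
rf_pair_energy(1, 1, 1.4, p)    # 0         (exactly, at the cutoff)

pr <- scan_profile(probe_config(c(1, -1), c(1, -1), scheme = "group",
                                grid = c(1.2, 1.6, 1e-3)))
find_discontinuities(pr, "energy")
#>   location       jump
#> 1   1.3995 -0.9994501
```

The single flagged jump sits at the 1.4 nm cutoff: when the centre distance
of the two dipoles crosses $R_{rf}$, the whole four-term molecular energy
(−1 kJ/mol at that geometry) switches off at once.  Under the atomistic rule
the same scan is continuous (each atomic term vanishes at the cutoff) but its
force profile spikes at the atomic crossing distances — the two faces of
cutoff noise.

Building and running a water system:

```r
w <- build_water_box(216, water_box_edge(216), seed = 1)
w
#> <md_system> 648 atoms, 216 molecules, 216 charge groups
#>   solute 0 / solvent 648 atoms; 648 constraints; box 1.8644 x 1.8644 x 1.8644 nm
w <- assign_maxwell_velocities(w, 298.15, seed = 2)
run <- run_simulation(w, scheme_preset("AT", r_short = 0.9, r_long = 0.9),
                      md_protocol(n_steps = 5000, eps_rf = 78,
                                  log_interval = 100))
```

The full desk-scale comparison — AT versus CG(OW) on 216 waters at a 0.9 nm
cutoff, with re-evaluation asymmetry, RDF structure at the cutoff and bath
temperatures — is one call (several minutes of compute):

```r
study <- cutoff_artifact_study(n_water = 216, r_cut = 0.9,
                               t_equil = 10, t_prod = 50, seeds = 1:3)
study
#> <artifact_study> 216 waters, cutoff 0.90 nm, 3 seed(s), 10 + 50 ps
#>   mean dE_vv  AT->CG(OW): +10318.64 kJ/mol   CG(OW)->AT: +202.83 kJ/mol
#>   RDF |dg| near cutoff: 1.018  (baseline SD 0.1270, ratio 8.0)
#>   mean solvent T: AT 306.42 K, CG 437.60 K (offset +131.17 K)
```

Both re-evaluation directions are positive (each scheme generates
configurations most favourable to itself) and the AT→CG direction is far
larger, the RDFs split sharply at the cutoff radius, and the group-based run
needs a hotter bath — the three signatures of cutoff artifacts, hugely
amplified by the deliberately small 0.9 nm cutoff.

A thin command-line surface wraps the same functions
(`inst/cli/cutoffmd build-water | simulate | probe1d | analyze | reeval`).

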