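---
title: "Cutoff schemes, reaction-field electrostatics and their artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cutoff schemes, reaction-field electrostatics and their artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cutoffmd)
```

## The model

`cutoffmd` is a minimal periodic molecular dynamics engine built to study one
question: how does the *bookkeeping* of nonbonded interactions — which pairs
interact, decided how, updated when — shape the physics a simulation reports?

Electrostatics between point charges $q_i, q_j$ at distance $r_{ij}$ are
treated with a reaction-field (RF) term that represents the medium beyond the
cutoff $R_{rf}$ as a homogeneous dielectric of permittivity
$\varepsilon_{rf}$:

$$V^{el}_{ij} = \frac{q_i q_j}{4\pi\varepsilon_0}\left[
  \frac{1}{r_{ij}} - \frac{\tfrac12 C_{rf}\, r_{ij}^2}{R_{rf}^3}
  - \frac{1-\tfrac12 C_{rf}}{R_{rf}}\right],
  \qquad C_{rf} = \frac{2(\varepsilon_{rf}-1)}{2\varepsilon_{rf}+1}.$$

With this generating formula for $C_{rf}$ (zero ionic strength, unit
dielectric inside the cutoff) the pair energy is *exactly* zero at
$r_{ij}=R_{rf}$; the implementation groups the terms as
$(1/r - 1/R) - \tfrac12 C_{rf}(r^2-R^2)/R^3$ so the zero also holds in
floating point.  Lennard-Jones interactions ($C_{12}/r^{12}-C_6/r^6$) ride on
the same pairlist with no shift and no long-range dispersion correction,
deliberately: the package isolates cutoff-scheme effects, and any additional
smoothing would blur them.

A **cutoff scheme** decides which pairs enter the sum:

* **atomistic (AT)** — every atom is its own interaction entity; a pair of
  atoms interacts iff their distance is below the cutoff.  Each atomic term
  vanishes at $R_{rf}$, so the molecular energy is continuous in the
  separation — but molecular *forces* change slope whenever an atom pair
  drops out, producing irregular force spikes at the cutoff.
* **charge-group (CG)** — atoms are grouped into (ideally neutral) charge
  groups; if the group *centres* are within the cutoff, *all* atom pairs of
  the two groups interact at their atomic distances, including atoms beyond
  $R_{rf}$.  Group inclusion keeps truncated interactions at dipole–dipole
  order ($r^{-3}$ rather than $r^{-1}$), but the energy now *jumps* when a
  centre pair crosses the cutoff.  The centre is either the centre of
  geometry (`CG(cog)`) or a designated atom such as the water oxygen
  (`CG(OW)`).
* **solute-atomistic (SA)** — solute atoms are individual entities while
  solvent molecules remain whole charge groups; the mixed rule of the 1D
  probe below.

The **twin-range (TR)** pairlist evaluates short-range pairs
($r < R_{short}$) every step from a list rebuilt every $n$ steps;
intermediate-range pairs ($R_{short} \le r < R_{long} = R_{rf}$) are
evaluated only at list rebuilds, and their forces, energy decomposition and
virial are frozen in a cache that is re-added unchanged in between.  An
update interval of 1 is the single-range (SR) limit; the implementation then
merges the two ranges into one canonically ordered list, which makes the
interval-1 twin-range run bit-identical to a run with a single cutoff at
$R_{long}$.

Dynamics are leapfrog with SHAKE (iterative bond restoration to relative
tolerance $10^{-4}$ on squared lengths, velocity corrections applied),
separate solute and solvent weak-coupling temperature baths
($\lambda = \sqrt{1 + (\Delta t/\tau_T)(T_{ref}/T - 1)}$, applied to the
post-SHAKE half-step velocities of each bath), and an optional isotropic
weak-coupling barostat
($\mu = (1-\kappa_T(\Delta t/\tau_P)(P_{ref}-P))^{1/3}$).  The pressure uses
the atomically accumulated pair virial $\Xi = -\tfrac12\sum r_{ij}\cdot
F_{ij}$, with the twin-range cache freezing the intermediate-range virial
alongside its forces.  Reported kinetic energies use the on-step average
$(v(t-\Delta t/2)+v(t+\Delta t/2))/2$; the thermostat uses the half-step
velocities it actually rescales.

## Defaults and their provenance

| parameter | default | note |
|---|---|---|
| timestep | 2 fs | with SHAKE-rigid molecules |
| cutoffs $R_{short}/R_{long}$ | 0.8 / 1.4 nm | pairlist update every 5 steps (10 fs) |
| $\varepsilon_{rf}$ | 61 (solute runs), 78 (pure water) | both exposed as config |
| baths | 298.15 K, $\tau_T$ = 0.1 ps, per subsystem | weak coupling |
| barostat | 1 atm, $\tau_P$ = 0.5 ps, $\kappa_T$ = 4.575e-4 (water: 7.51e-4) (kJ mol$^{-1}$ nm$^{-3}$)$^{-1}$ | off unless enabled |
| SHAKE tolerance | $10^{-4}$ relative | on squared bond lengths |
| water model | SPC: $q_O=-0.82$, $q_H=+0.41$ e, $d_{OH}=0.1$ nm, 109.47°; O–O LJ $C_6=2.61735\times10^{-3}$, $C_{12}=2.634129\times10^{-6}$ | rigid 3-site |

Units are nm, ps, u, e, kJ/mol throughout
($f_{el} = 138.935458$ kJ mol$^{-1}$ nm e$^{-2}$,
$k_B = 8.31446\times10^{-3}$ kJ mol$^{-1}$ K$^{-1}$,
1 atm = 0.0610194 kJ mol$^{-1}$ nm$^{-3}$).

Numerical conventions that were genuinely open and are fixed here:

* **Tie handling at the cutoff** is strictly `<`, with the half-open
  intermediate shell $[R_{short}, R_{long})$.
* **Excluded intramolecular pairs receive no reaction-field contribution.**
  For rigid molecules the omitted term is a constant energy offset whose
  forces are absorbed by the constraints; cross-scheme energy differences are
  unaffected because both schemes omit the same term.
* **Minimum image** is applied per interaction on orthorhombic boxes only;
  stored coordinates are never wrapped, so constraints and centres of
  geometry never straddle a boundary.  Boxes must exceed twice $R_{long}$.
* **Thermostat ordering**: coupling is applied after SHAKE so constrained
  degrees of freedom are not double-counted; per-bath degrees of freedom are
  $3N - N_{constraints}$ with no centre-of-mass correction (COM removal is
  off at desk scale).
* **Cached intermediate-range energies** are simply re-added to the
  potential between updates; they carry no special thermostat bookkeeping.
* **Pair lists are canonically $(i,j)$-sorted**, so the cell-list and
  brute-force paths return identical structures and runs are bit-reproducible.
  The cell list engages above 200 entities when every box dimension admits
  three cells of edge $R_{long}$; otherwise the $O(N^2)$ path runs (at the
  bundled system sizes the two are indistinguishable in time).

## The synthetic systems

`build_water_box()` places rigid SPC-parameterized waters on the smallest
enclosing cubic lattice, jitters sites by ±0.01 nm, orients each molecule by
a random quaternion, and guarantees a 0.24 nm minimum O–O separation (it
refuses boxes too small to honour it).  `build_toy_solute()` builds a chain
of neutral dipolar two-atom residues (±0.4 e, 0.1 nm; 0.38 nm constrained
virtual bonds; a small oxygen-sized LJ site per atom) — enough structure to
exercise the solute-atomistic scheme and the solute/solvent energy
decomposition, with no pretension of being a protein.
`assign_maxwell_velocities()` draws per-component Gaussian velocities at the
target temperature and projects out components along constrained bonds.

What these generators emulate is the *geometry and interaction bookkeeping*
of a solvated biomolecular system; what they do not emulate is protein
topology, ions, or any calibrated force field beyond SPC water.  Passing
tests therefore demonstrate that the cutoff-scheme machinery behaves as
specified, and that the qualitative solvent artifacts of the schemes
reproduce — not that any protein observable is predicted.

## The 1D probe

Two rigid diatomics (bond 0.1 nm) are translated along the x axis and their
interaction energy and axial force computed under the atomistic, group and
mixed inclusion rules on a 10^-3 nm grid.  Molecular orientation matters more
than one might expect, and `probe_config()` exposes it:

* both bonds perpendicular to the axis and parallel (the default): the group
  scheme shows its full discontinuity at the centre crossing
  (≈ −1 kJ mol$^{-1}$ for unit-charge dipoles at $R_{rf}=1.4$ nm) while the
  atomistic energy is continuous with force spikes at the two atomic
  crossing distances;
* molecule A along the axis, molecule B perpendicular: B's atoms are
  equidistant from every A atom, so the mixed rule's toggled term is
  $q_a(q_3+q_4)V(r) = 0$ for a neutral B — the mixed scheme is *exactly*
  continuous at the centre crossings, the property that motivates the
  solute-atomistic scheme.

No single orientation shows both extremes at once: with parallel
perpendicular bonds both A atoms cross B's centre simultaneously, which makes
the mixed jump coincide with the group jump, and with A collinear the group
dipole–dipole jump cancels by symmetry.  The package therefore probes each
property in the geometry where it is exact, and `find_discontinuities()`
(a jump is flagged when it exceeds 10× the median neighbouring change within
a ±25-interval window, with a tiny absolute floor so flat stretches stay
quiet) localizes the jumps.

## The scaled-down artifact study

`cutoff_artifact_study()` reruns the package's central comparison at desk
scale: 216 SPC waters at ambient density (box edge ≈ 1.865 nm), a single
cutoff $R_{short}=R_{long}=0.9$ nm, $\varepsilon_{rf}=78$, 10 ps
equilibration + 50 ps production per run, atomistic versus CG(OW) schemes,
three seeds.  These sizes were chosen as the smallest geometry that keeps the
box above twice the cutoff at liquid density while making the artifacts large
and quick to measure; the runs are NVT because barostat shrinkage would push
the box below the minimum-image bound.  Three signatures are extracted:

1. **Re-evaluation asymmetry.**  Stored frames from each run are re-evaluated
   under the other scheme (always single-range, fresh pairlist per frame) and
   the mean solvent–solvent electrostatic change $\Delta E = E_{alt} -
   E_{orig}$ recorded.  Configurations are most favourable for the scheme
   that generated them, so both directions are positive — and AT→CG(OW) is
   much larger, because the atomistic scheme structures the solvent at the
   cutoff and the group re-evaluation reintroduces the interactions those
   configurations pushed outside.
2. **RDF structure at the cutoff.**  The O–O radial distribution functions
   of the two schemes agree in the first solvation shells but split near
   $r = R$; the study reports the maximum $|g_{AT}-g_{CG}|$ within 0.05 nm of
   the cutoff against the baseline spread of the same difference at
   0.6–0.8 nm.
3. **Bath temperatures.**  Group-based cutoff noise (energy jumps at centre
   crossings) demands more heat removal; the CG solvent bath runs at or above
   the AT bath.

A 0.9 nm cutoff in a 1.9 nm box makes both artifacts *much* larger than at
the standard 0.8/1.4 nm setting — the cutoff sits inside the second solvation
shell, molecular pair energies at the boundary are of kJ/mol order, and the
weak-coupling baths absorb a correspondingly larger stationary heat flow, so
the CG run sits well above its reference temperature.  That amplification is
the point of the desk-scale geometry: the signatures are unambiguous within
50 ps, whereas at 1.4 nm they need nanoseconds to resolve.  The direction and
ordering of all three signatures, not their magnitudes, are the reproducible
content.

## Degenerate inputs and numerical edges

* A scheme with singleton charge groups is numerically identical to the
  atomistic scheme (tested to $10^{-12}$), and twin-range with per-step
  updates is bit-identical to single-range — two degeneracies that anchor the
  pairlist machinery.
* SHAKE aborts with diagnostics after 500 sweeps; the velocity projection
  after Maxwell assignment iterates to $10^{-12}$.
* With the thermostat off and no entity pair crossing a cutoff, total energy
  is conserved; the NVE check integrates a bound (+1 e / −1 e) pair with
  oxygen-sized LJ cores at 0.5 fs and measures drift as the slope of a
  linear fit to $E(t)$ — the pair oscillates deep in a stiff well, so any
  point-to-point measure would read vibrational aliasing as drift.
* `rmsd100()` flags chains below the validity of its normalization
  ($1+\ln\sqrt{N/100} \le 0$) rather than extrapolating; the hydrogen-bond
  criterion thresholds the donor–acceptor distance by default, with a
  switch for the conventional hydrogen–acceptor reading.
* The dipole–dipole correlation function bins pairs by oxygen–oxygen
  (designated-site) distance, with the centre of geometry as fallback; the
  convention is recorded in the output metadata.

## Known limitations

Orthorhombic boxes only; no Ewald/P3M reference, no switching functions, no
dispersion correction, no ions, no protein topologies.  Re-analysis
recomputes electrostatics (and optionally LJ) but never free energies.  The
energy-conservation and temperature-offset magnitudes at the desk-scale
cutoff are far larger than production MD values and should be read only
through the cross-scheme comparisons above.
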