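---
title: "The split membrane model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The split membrane model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitmem)
```

## The model

Lateral lipid mixing is the slow degree of freedom in all-atom membrane
simulations: a phospholipid needs tens of microseconds to diffuse across a
membrane patch, because its headgroup and its two acyl chains must move as
one large molecule through a crowded bilayer. The split membrane model
removes that constraint. Each phospholipid is cut at the glycerol backbone
— the C1–C2 carbon–carbon bond on the path leading to the phosphate — into
two molecules: a *head* (phosphocholine/phosphate fragment plus glycerol
C1) and a *tail* (the C2 fragment carrying both acyl chains). Each cut end
is capped with a **virtual site** (V1 on heads, V2 on tails): a
construction-defined pseudo-atom with zero mass, zero charge and no
Lennard-Jones interactions, bonded to the cut-side carbon so the cut
valence and local geometry are preserved.

Without covalent head–tail bonds the bilayer would evaporate, so three
flat-bottomed layer potentials on the distance $d = |z - z_\mathrm{COM}|$
from the membrane centre of mass hold it together:

| selection | form | k (kJ mol⁻¹ nm⁻²) | r₀ (nm) |
|---|---|---|---|
| water oxygens | inverted | 2.5 | 2.5 |
| C1 head anchors | standard | 10 | 3.3 (2.8 for pure POPC) |
| C2 tail anchors | standard | 50 | 1.0 |

with $U = \tfrac12 k\,(d - r_0)^2$ outside the well for the standard form,
and $U = \tfrac12 k\,(r_0 - d)^2$ *inside* $r_0$ for the inverted form
(water is pushed out of the membrane interior, heads kept near the
surface, tails kept near the midplane). The harmonic flat-bottom form is a
design decision: the published description names the potential and its
parameters but not the formula, and this is the standard functional form
for flat-bottomed positional restraints; "kJ/mol" force constants are
interpreted in the standard kJ mol⁻¹ nm⁻² units. `flat_bottom_energy()`
implements the potential exactly (energy and force are continuous at
$r_0$; the force is the analytic $-\mathrm{d}U/\mathrm{d}z$, verified
against finite differences in the tests).

The tighter 2.8 nm head restraint is kept as the `pure_POPC` variant of
`default_restraints()`: it reproduces density profiles slightly better,
while the looser 3.3 nm is used for mixed membranes, where it also
enhances diffusion further.

### Reference frame of the restraints

The model defines restraint distances from the membrane COM, which moves
during a simulation, while engine-format position restraints need fixed
reference coordinates. Both are supported and neither is claimed to be the
original mechanism (the published description does not say): `posres` mode
pins the reference to the membrane COM of the emission frame and records
the approximation in the emitted manifest; `pull` mode emits COM-pull
sections that stay relative to the instantaneous membrane group.

## Splitting

`split_lipid()` is a pure topology transformation governed by a
`split_spec` (cut bond, head/tail atom partition, anchors). The defaults
are derived from connectivity: remove the cut bond and take the two
connected components, which reproduces the head = phosphate-side /
tail = chains-side partition. Contracts enforced by the tests:

* every atom lands in exactly one moiety with unchanged name, type, mass
  and charge; per-lipid and total charge are conserved to 1e-6 e;
* the cut bond is removed; each moiety gains exactly one virtual-site bond
  carrying the original cut-bond parameters, so
  $n_\mathrm{bonds}(head) + n_\mathrm{bonds}(tail) =
  n_\mathrm{bonds}(orig) - 1 + 2$;
* bonded terms spanning the cut (angles, dihedrals, pairs, exclusions) are
  **dropped**, not re-expressed through the virtual sites. Only the cut
  bond's valence is preserved — anything more would be invention beyond
  the stated model;
* moieties may carry non-integer net charge (a PS head keeps the lipid's
  −1 e). Charges are never renormalised, since that would alter the force
  field; `split_system()` returns a per-moiety charge report instead.

Virtual sites use a 3-atom out-of-plane construction
($r = r_i + a\,r_{ij} + b\,r_{ik} + c\,(r_{ij} \times r_{ik})$, exactly
rotation/translation equivariant) from the cut atom and two bonded
neighbours, falling back to a 2-atom linear construction at terminal cuts.
Parameters are fitted per moiety species from the first molecule of the
input frame so that the site lands on the removed neighbour's position;
in the split frame every virtual site is *placed* at that exact position,
making a freshly split system geometrically identical to its parent. The
construction is our convention, documented as such — the original
implementation's virtual-site function type is not stated.

Sphingomyelin has no glycerol; its spec declares the analogous backbone
bond. In the synthetic fixtures PSM shares the glycerophospholipid
skeleton, so the same C1–C2 names apply; real force-field topologies
override the spec per species.

## Merging

Reunification selects, for each tail, the closest head — implemented as
greedy acceptance over all candidate head–tail anchor distances sorted
ascending, with deterministic (head id, tail id) tie-breaking. Distances
between the C1 and C2 anchors (the formerly bonded atoms) use the minimum
image in xy and the plain difference in z: a head must not be matched to a
partner through the membrane. Two strengthenings beyond the one-line
published rule, both deliberate:

* **class-restricted matching**: pairing is a bijection within each
  (leaflet, lipid type) class, because merging a POPS tail with a POPC
  head would corrupt chemistry, and cross-leaflet pairing is physically
  meaningless. Count mismatches abort with the offending class named.
* an **optimal** strategy (O(n³) Hungarian assignment, cross-checked
  against brute-force enumeration on small instances in the tests) for
  pathological configurations where greedy is suboptimal; greedy remains
  the default since it matches the stated rule and equals the optimum
  whenever nearest neighbours are mutual.

`apply_merge()` removes the virtual sites, restores the stored pre-split
topology (cut bond and all dropped terms included), reorders atoms to the
original species order and leaves real-atom coordinates untouched, so
split → merge on an unmoved frame is the identity on topology and
coordinates — asserted bitwise in the acceptance suite. After a real
simulation some junctions are long; `strain_report()` lists pairs above a
threshold (default 0.3 nm) and emits headgroup-fixing restraint files for
the recommended recipe: minimise, then briefly re-equilibrate with head
positions fixed so the tails move toward their heads.

## Analysis battery

* **Lateral diffusion.** `lateral_msd()` tracks per-molecule lateral COMs,
  unwrapped across the periodic boundary (consecutive-frame nearest-image
  continuity; exact unwrapped coordinates are used when the trajectory
  carries them). The averaging over all time origins uses the FFT
  algorithm, cross-checked against a quadratic brute-force oracle.
  `fit_diffusion()` applies the 2D Einstein relation $D =$ slope$/4$ on a
  stated window — the published analysis uses 50–400 ns, where the MSD is
  linear. The divisor 4 (not 6) is forced by the *lateral* MSD and by the
  diffusion-time arithmetic below. Drift correction defaults to `none`,
  matching plain displacement analysis; system- and leaflet-COM removal
  are optional because the published convention is not stated.
* **Diffusion time and speedup.** $\tau = d^2 / 4D$, reported in μs for
  $d = 20$ nm. The published table's footnote prints "20 nm²", but only a
  20 nm displacement (MSD = 400 nm²) reproduces all six printed times, so
  that reading is implemented. The error convention on published D values
  (fit error vs replicas) is likewise unstated; `fit_diffusion()` reports
  a two-halves block estimate over molecules and documents it as its own
  choice.
* **Order parameters.** $S_{CD} = \langle (3\cos^2\theta - 1)/2 \rangle$
  per chain carbon against the +z normal. A `reconstructed` hydrogen mode
  builds ideal tetrahedral hydrogens from the three consecutive carbons so
  united-atom fixtures are analysable; an all-trans chain aligned with z
  gives exactly −0.5, isotropic chains give 0 (Monte-Carlo checked).
* **P–N angle** is measured against the *outward* leaflet normal; means
  near 90° for relaxed membranes force this normal-referenced convention
  (a plane-referenced angle would centre near 0°).
* **Density profiles** re-centre z on the membrane COM per frame and
  convert amu/nm³ to kg/m³; the integral times box area recovers the
  selected mass (±1% asserted).
* **Area per lipid** is box xy-area over lipids per leaflet; **thickness**
  is the distance between the mean z of upper and lower reference atoms
  (P, N or C2); the **RDF** supports spherical-shell 3D and annulus
  lateral-2D normalisations with minimum-image distances.

## Synthetic fixtures: what they do and do not establish

`build_bilayer()` places simplified lipids (52 pseudo-atoms for PC-like
species: 20 head + 32 tail, correct P/N/C1/C2/chain-carbon names, neutral
PC/PE/SM, −1 e PS/PA) on a square lattice at the target area per lipid
(default 0.658 nm², the published pure-POPC value), all-trans tails toward
the midplane, P planes at ±1.9 nm (thickness 3.8 nm, a typical PC bilayer),
in-plane P→N vectors, a water slab (default 6 waters per lipid — enough to
exercise the water-restraint machinery while keeping fixtures small) and
neutralising counterions. Compositions follow the published per-leaflet
tables; leaflet species placement is a seeded shuffle and all generators
are byte-deterministic per seed. `brownian_trajectory()` draws lateral
Gaussian steps with variance $2 D \Delta t$ per axis — its exact MSD slope
is the oracle for the Einstein-relation machinery (defaults: 500
particles, D = 0.05 nm²/ns, within the published 0.005–0.1 nm²/ns range,
dt = 0.1 ns, 2000 frames).

A green test on these fixtures establishes the *machinery*: bookkeeping
exactness of split/merge, unit correctness, estimator consistency, format
fidelity. It does **not** establish the physics of the published
observables — equilibrium areas per lipid, density profiles, order
parameter profiles or absolute diffusion coefficients of real membranes
require microsecond MD with the real force field and are out of scope; the
published *arithmetic* (diffusion times, speedups, restraint parameters,
composition totals) is reproduced exactly from the printed inputs instead.

## Numerical choices and edge cases

* Orthorhombic boxes only; triclinic input is rejected with a clear error.
* A lipid anchored exactly at the membrane COM is assigned to the *upper*
  leaflet with a warning (the convention is ours; the case has measure
  zero in real data).
* The membrane COM is mass-weighted over all lipid-species atoms by
  default and overridable by selection; COM reference for emitted
  restraints defaults to the initial frame (see above).
* GRO I/O is fixed-column and deterministic (identical input → identical
  bytes); parse errors report line numbers; velocities are preserved when
  present and never fabricated. The ITP parser keeps unknown force-field
  sections verbatim, so splitting real Slipids files does not require
  understanding every parameter line; `#include`/`#ifdef` lines are
  recorded, not evaluated. Multi-frame GRO is the native trajectory format
  so the test path has no binary dependencies.
* Merge ties are broken lexicographically; all generators restore the
  caller's RNG state.

## Known limitations

* Cross-cut angles and dihedrals are dropped on splitting; near the cut
  the moieties are slightly floppier than the parent force field until
  merged (consistent with the model's slightly reduced glycerol-region
  order).
* The emitted posres reference z is frozen at the emission frame's COM; a
  drifting membrane needs the pull-mode emitter.
* `order_parameters()`'s reconstructed mode reports interior carbons only.
* Proteins and cholesterol are passed through unsplit by design; running
  the MD itself (thermostats, PME, constraints) is out of scope.
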