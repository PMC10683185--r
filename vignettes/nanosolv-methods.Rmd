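---
title: "Models and methods in nanosolv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nanosolv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

nanosolv studies how a drug-carrier nanotube and its drug complexes are
hydrated: a rigid solute is fixed in a periodic cubic box of explicit
three-site water, the canonical ensemble is sampled by Metropolis Monte
Carlo, and free-energy perturbation over a coupling parameter gives
solvation free energies that combine, through a thermodynamic cycle,
into the association free energy of the drug-carrier complex.  The
concrete system it emulates is sulfasalazine (SSZ, keto and enol
tautomers) on the outer wall of a hydrogen-capped zigzag (9,0)
boron-nitride nanotube (B99N99).  This vignette records the models, the
parameters that matter, and the design decisions taken where the
problem statement was open.

## Energy model

All bodies are rigid, so the configurational energy is purely
intermolecular:

* **Water-water**: a three-site transferable intermolecular potential —
  point charges on O (-0.834 e) and H (+0.417 e), one Lennard-Jones
  site on O (epsilon = 0.1521 kcal/mol, sigma = 3.1507 A), O-H =
  0.9572 A, H-O-H = 104.52 deg.  The published description names the
  three-site family without printing values; these are the standard
  parameters of that family and every value is exposed in
  `water_model()`.
* **Solute-water**: Lennard-Jones plus Coulomb per site pair,
  `4 eps [(sig/r)^12 - (sig/r)^6] + k q_i q_j / r` with
  k = 332.06 kcal A/(mol e^2), Lorentz-Berthelot mixing against the
  water oxygen, and the published per-site LJ table (B, N on the tube;
  C, N, S, H, "H on C" on the drug).  Two registry quirks are kept
  deliberately: the published "H" row carries sigma = 0.094 A, almost
  certainly a misprint, and is used exactly as printed (it is flagged in
  the registry and can be overridden via `forcefield(sites = ...)`);
  and the table has no row for solute oxygen, so O sites fall back to
  the water-oxygen parameters.  Both choices are visible in
  `load_reference_table("lj")`.

**Cutoff convention.**  Water-water pairs use a molecule-centre (O-O)
spherical cutoff of 9.5 A with no long-range correction — the published
molecular-dynamics section of the same study truncates there, and the
Monte Carlo section is silent.  Whole molecules are included or
excluded together, with the O-O minimum-image shift applied to all nine
site pairs so molecules are never split across images.  Solute-water
interactions are summed in full under minimum image: the tube is
comparable in length to the box, so no single-centre cutoff is
meaningful for it, and because the solute is fixed the cost of the full
sum is linear in the number of waters.  `interaction_energy()` for two
generic small molecules implements the centre-centre cutoff rule.  For
boxes smaller than twice the cutoff (used in tests) the minimum-image
sum simply sees at most one image of each molecule.

## Monte Carlo sampling

One attempted move ("configuration") selects a water uniformly,
translates it by independent uniform displacements in +/-0.13 A per
Cartesian axis, and rotates it by a uniform angle in +/-10 deg about a
uniformly random axis through its oxygen.  The reference protocol
states the amplitudes and a ~50% acceptance; whether the translation
bound is per-axis or a vector norm is not stated, and per-axis was
chosen (configurable).  Rotation about the O atom keeps the proposal
symmetric, as the Metropolis rule `min(1, exp(-dE/RT))` requires.  At
298 K and 0.993 g/cm3 these amplitudes give ~52% acceptance here.

The energy is tracked as a running sum of local move differences; a
full recomputation every 1e5 moves bounds floating-point drift (the
maximum observed drift is reported on every trajectory and is ~1e-12
kcal/mol at test scale).  All randomness is drawn from R's RNG in a
frozen order (molecule, translation, rotation axis, angle, acceptance),
so a seed makes runs bit-identical; the compiled sampler and the
R-level `propose_move()`/`metropolis_accept()` implement identical
conventions, which the test suite cross-checks.

Equilibration defaults to 10% of production, but hydration-structure
runs here use much longer equilibration (1-2e6 moves for ~830 waters,
i.e. the same per-water relaxation budget as the reference 1e7-move
runs at ~4000 waters), because first-shell structure around the tube
relaxes diffusively under 0.13 A moves.

## Synthetic structures

No coordinates are deposited for this system, so every input is
generated:

* **Tube** (`build_bnnt()`): a honeycomb lattice rolled onto a
  cylinder, rings of 9 atoms alternating B and N, with the radius
  chosen as `sqrt(3) b / (4 sin(pi/2n))` so that *every*
  nearest-neighbour distance equals the B-N bond length (1.45 A
  default, inside the published relaxed range 1.450-1.460 A).  For
  n = 9 this gives R = 3.616 A against the published relaxed 3.67 A —
  pure arc-length rolling would give 3.60 A with shortened
  circumferential bonds; the relaxed DFT geometry itself is not
  recoverable from the text.  22 rings give B99N99 at 22.5 A; both rims
  are zigzag edges capped by one H per rim atom (B-H 1.19 A, N-H
  1.01 A, along the severed axial bond; the text says only "saturated
  with hydrogen").  B and N carry +/-0.83 e (the published average
  Mulliken charges); cap hydrogens absorb any residual so the tube is
  exactly neutral.
* **Drug** (`build_ssz_fixture()`): a rigid 42-atom sulfasalazine
  (C18O5N4SH14) with idealized planar-backbone geometry from standard
  bond lengths.  The published Mulliken table covers 13 roles (C1, C2,
  O1-O3, N1-N4, S, O(S), H2, H3); both sulfonyl oxygens share the
  single O(S) value, untabulated carbons stay at zero, and the residual
  (+1.23 e for either tautomer) is spread uniformly over the twelve
  untabulated hydrogens to force exact neutrality.  The keto/enol
  difference is the O1 bond length (C=O 1.22 vs C-OH 1.36 A) and the
  position of the mobile proton (on N1 vs on O1).  The solvation
  machinery is insensitive to fine internal geometry; results that
  depend on the true optimized structures are out of scope.
* **Complex** (`place_complex()`): only the closest-contact pair and
  the gap are contractual.  The pose is a deterministic construction:
  the site's anchor atom (carbonyl O over B or N, sulfonyl O over B,
  pyridine N over B) is aimed along its local bond direction at the
  surface atom nearest the tube's axial midplane, the body is tilted in
  2-degree steps until the anchor is the closest atom, then slid
  radially until the minimum cross-body distance equals the gap.  With
  the keto drug and `carbonyl_v2`, gap 2.55 A reproduces the published
  carbonyl-O-over-B contact.  For the enol tautomer the carboxyl
  hydrogen can remain the closest contact; the global gap contract
  still holds.
* **Solvation** (`solvate()`): waters seeded on a jittered simple-cubic
  lattice at the requested density (0.993 g/cm3 = 0.0332 molecules/A^3;
  a 50 A box holds ~4150 before carving), randomly oriented, then any
  water with O within 2.6 A of a solute atom removed.  The carve
  threshold is not published; 2.6 A avoids initial overlaps and
  reproduces the published depletion (~60-190 fewer waters with the
  tube and complexes present in a 50 A box).

What the generator deliberately does **not** emulate: DFT-relaxed
geometry (bond-length variation at the binding site), per-atom charge
heterogeneity (a single averaged +/-0.83 e is used), solute
flexibility, and counter-ions.  Tests passing on these fixtures
validate the simulation and estimation machinery under the stated
conditions, not the quantum-chemical specifics of real SSZ-BNNT
binding.

## Free-energy perturbation

The Zwanzig estimator `dG(A->B) = -RT ln <exp(-(E_B - E_A)/RT)>_A` is
computed with a log-sum-exp.  Solvation legs use staged annihilation: a
coupling parameter scales solute-water charges linearly and the
solute-water Lennard-Jones term through a soft-core form
`4 eps lam [ (s6/d)^2 - s6/d ]`, `d = alpha (1 - lam) s6 + r^6`,
alpha = 0.5, which removes the end-point singularity as atoms vanish.
The default schedule has 11 intervals denser near lambda = 0; windows
are simulated from lambda = 1 downwards, each starting from the
previous window's final configuration, with per-window seeds derived
from the run seed.  `double_wide` mode (default) simulates at every
window value and averages the forward and negated backward estimates of
each interval; statistical errors are block averages over 10 blocks.
An effective-sample-size warning fires when a window's exponential
average rests on fewer than 10% of its samples.

Two practical lessons are recorded in the test fixtures: the
annihilation chain relaxes *diffusively* (the cavity around a
disappearing solute fills by water diffusion), so per-window
equilibration must be generous or the forward and reverse legs
hysterese; and with the reference +/-0.13 A amplitudes that relaxation
is slow, so the estimator cross-checks use larger test-local amplitudes
(+/-0.35 A, +/-25 deg).  Block standard errors under-estimate when
samples are autocorrelated; the suite's stochastic comparisons were
verified to pass at their stated confidence with margin.

For a rigid solute the gas-phase annihilation leg is exactly zero (no
intramolecular terms, no solvent), so `dG_solv = -dG_sol(A->0)`; the
gas leg is an explicit field so the convention is auditable.  The
association cycle is
`dG_ass = dG_sol(drug->0) + dG_sol(tube->0) - dG_sol(complex->0)`,
with a second entry point taking solvation free energies instead.  The
shipped free-energy table closes this cycle on all seven published
complex rows; one leg is printed without its minus sign (the corrected
value is carried alongside the printed one) and one row only to two
decimals.

## Hydration structure

`cylindrical_rdf()` bins water-oxygen distance from the tube axis into
0.2 A shells of full box height: `g(r) = rho(r)/rho_bulk` with
`rho_bulk = N/V`.  Full-height shells (no axial truncation at the tube
ends) keep peak heights comparable run to run; regions beyond the tube
ends therefore dilute the contrast but do not move peak positions.
Hydrogens are excluded, as is conventional for hydration shells.  The
bulk normalisation ignores the tube's excluded volume, which biases g
upward by ~3% in a 30 A box — inside the 1 +/- 0.1 bulk-recovery check.

A reproducible scaled-down protocol (half-length capped tube, 30 A box,
reference move amplitudes, >= 5e5 production moves) yields a converged
first outer peak at **6.7 A** from the axis (3.08 A from the wall) and
bulk behaviour beyond 9 A.  The published figure places this peak at
6 A, i.e. 2.33 A from the published 3.67 A surface.  With the published
LJ table that distance lies far up the B/N-O repulsive wall (the B-O
pair minimum is at 3.66 A), and pure electrostatics cannot pull an
oxygen there: directly over a B(+0.83) site the three adjacent
N(-0.83) at ~2.7 A repel the water oxygen more strongly than the B
attracts it.  Under the published parameter set with uniform averaged
charges, a 2.33 A contact peak is therefore not reproducible; the 6.7 A
result is this model's converged answer, and the corresponding
acceptance test records the published 6 +/- 0.5 A band and its failure
rather than adjusting either the band or the generator.

## Numerical choices and limitations

* Units: kcal/mol, Angstrom, Kelvin, elementary charge;
  R = 1.98720425e-3 kcal/(mol K); Hartree-to-kcal/mol = 627.5095
  (`hartree_to_kcal`); the published kcal columns are authoritative
  where the Hartree column disagrees by rounding.
* The local-virial bookkeeping follows the tabulated data:
  `virial_consistency()` returns `lap - 4 (2G + V)`, the standard
  atomic-unit relation; the equation as printed in the source omits the
  factor, and its own table satisfies the corrected form to ~5e-6 a.u.
* Degenerate inputs: zero waters give an all-zero energy breakdown;
  `n_prod = 0` gives an empty series; a ghost solute annihilates for
  exactly 0; overlapping starting configurations abort with the
  offending molecule rather than propagating non-finite energies.
* Problem sizes in the shipped tests and acceptance script (63-830
  waters, 1e4-2e6 moves, 6 FEP windows) were chosen so the full suite
  and script each run in minutes on one CPU while every stochastic
  check retains the statistical power its tolerance needs.  Absolute
  hydration energies and solvation free energies of the real 4000-water
  system are not reproduced at this scale — they additionally require
  the unpublished DFT structures and per-atom charges — which is why
  the published energy tables enter as transcribed inputs to the
  bookkeeping layer instead.
* No Ewald summation, polarizability, NPT sampling, solute moves or
  conformation selection; the pyridinium nitrogen is fixed
  non-protonated (published pKa 0.6).
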