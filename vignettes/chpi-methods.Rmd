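---
title: "CH-pi detection and scoring: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CH-pi detection and scoring: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chpi)
```

## The problem

CH-pi interactions are weak attractive contacts between an aliphatic C-H
bond and the pi face of an aromatic ring. They are common in
protein-ligand complexes - carbohydrate ligands stacking on tryptophan
side chains are the textbook case - but typical empirical docking scores
contain no term for them: a methane poised perpendicularly over a benzene
ring scores only about -0.4 kcal/mol from the steric and hydrophobic
terms of the base score, far short of the roughly -1.5 kcal/mol that
high-level quantum-mechanical calculations assign to the dimer. This
package implements a pairwise empirical CH-pi term that can be added to
a re-implemented AutoDock-Vina-style base score, together with the
machinery used to detect CH-pi contacts in structures, re-derive the
term's parameters from reference dimer energy curves, and validate the
term by torsion grid searches.

## Geometry of a contact

For a C-H group and an aromatic ring the package computes (via
`chpi_geometry()`): the H-centroid distance *R*; the C-H-centroid angle
theta (180 degrees when the H points straight at the centroid); the
dihedral omega between the ring plane and the plane of the H and its two
nearest bonded ring atoms (90 degrees puts the H directly above a ring
edge); the angle theta1 between the carbon-centroid vector and the ring
normal; the tilt theta2 between the C-H axis and the ring normal; and the
horizontal/vertical offsets of the carbon from the centroid. A detected
contact (`detect_contacts()`) requires *R* <= 3.5 angstrom; residues with
any partial-occupancy atom or an average B-factor above 40 are excluded,
as are methyl hydrogens, whose torsional positions are not experimentally
determined (their coordinates are model-built, so they are still used in
energy evaluation, just not in mining). Contacts with theta1 < 35 and
theta2 < 35 degrees are flagged as strong. Reported angles are folded to
one ring face, so mirror-image poses aggregate identically.

## The energy model

The base score (`vina_base_energy()`) is the published empirical docking
function evaluated over intermolecular heavy-atom pairs within 8
angstrom of each other: two attractive gaussians and a quadratic soft
repulsion in the surface distance, a hydrophobic ramp, and an H-bond
ramp, with the published term weights and van der Waals radii (shipped in
`inst/extdata/base_score_constants.json`). Conformation-independent
contributions are omitted so that infinitely separated molecules score
exactly zero.

The CH-pi term comes in two forms. The hydrogen-dependent form
(`e_chpi_h()`) sums over every (aliphatic H, aromatic ring carbon) pair

```
e(R_HC) * f(theta2),   e(R) = -E_HC * alpha * exp(-((R - R0_HC) / (kappa * C_HC))^2)
```

with defaults `E_HC = 0.29` kcal/mol, `R0_HC = 3.58` angstrom and
`C_HC = 0.85`. The angular factor `f` is a clamped cosine of the directed
tilt angle: 1 when the C-H points straight at the ring along the normal,
0 at and beyond perpendicular. The direction matters: hydrogens pointing
*away* from the ring contribute nothing, which is also why a methane in
the canonical perpendicular pose interacts through its single ring-facing
hydrogen. Ring nitrogens (e.g. in histidine) are excluded from the sum;
only ring carbons carry the term. This is the mechanism behind the weak
histidine CH-pi energies relative to PHE/TYR/TRP: an imidazole brings
three ring carbons to the sum where a benzene brings six. The
hydrogen-independent form (`e_chpi_c()`) uses the same radial kernel on
(aliphatic carbon, ring carbon) distances with defaults `E_CC = 0.26`,
`R0_CC = 4.49`, `c_CC = 0.75` and no angular factor; it exists so the
term can operate inside scoring engines that never see hydrogens. The
combined score is `total = e_vina + w * e_chpi` (`total_energy()`); `w =
1` is used during parameter fitting and `w = 0.3` is the recommended
general-purpose weighting.

### The kernel's structural constants

The radial kernel carries two fixed implementation constants: a depth
fraction `alpha = 0.45` and a breadth factor `kappa = 4/3`. They are not
user parameters and are deliberately separate from `(E, R0, C)`. The
package fixes them, once, by requiring that the default parameter triples
reproduce four reference behaviors of the idealized methane-benzene
dimers (`dimer_anchors()`): the base score alone gives about -0.4
kcal/mol along the horizontal trace of the canonical perpendicular dimer
at 3.8 angstrom vertical separation; adding the hydrogen-dependent term
at unit weighting gives about -1.0 kcal/mol, approximately flat over the
ring face; and the six dimer orientations have vertical-scan optima
averaging 3.7 +/- 0.2 angstrom at -1.2 +/- 0.2 kcal/mol. A naive kernel
with per-pair depth `E_HC` at `R0_HC` cannot satisfy these anchors
simultaneously: on the ring axis all six H-carbon distances pass through
`R0_HC` together, which would force a combined well of about six times
the per-pair depth (about -1.9 kcal/mol) at too large a separation. The
depth fraction absorbs exactly this multi-counting. With the calibrated
constants the package computes t1 = -0.357, t2 = -1.000, t3 = 3.816
angstrom and t4 = -1.128 kcal/mol, all inside the anchor tolerances;
`scripts/acceptance.R` recomputes these numbers from scratch.

## Dimer laboratory

`build_monomer()` constructs an idealized planar benzene (C-C 1.391,
C-H 1.087 angstrom) and a tetrahedral methane (C-H 1.091 angstrom);
idealized geometry stands in for quantum-chemically optimized monomers,
a sub-0.01-angstrom difference that is negligible at the +/- 0.2
tolerances of the anchors. The six labeled dimer orientations are
encoded as documented rotation constants (`build_dimer()`): A, D and E
are vertex-down (one C-H on the ring axis pointing at the centroid, the
unit-angular-factor family) at azimuths 0/30/15 degrees; B and F are
edge-down (two hydrogens toward the ring) at azimuths 0/30; C is the
face-down tripod. The orientations other than vertex-down are defined
only pictorially in the source material, so their azimuths are package
conventions; at zero horizontal offset all six share the same
carbon-centroid distance, which is the property the fitting protocol
relies on. Vertical scans run 3.0-4.2 angstrom in 0.1 steps and 4.4-6.0
in 0.2 steps (22 points); horizontal scans run 0.0-1.4 toward a ring
carbon or 0.0-1.2 toward a bond midpoint in 0.1 steps, with the methane
orientation held fixed during horizontal displacement. Curve minima are
refined by a parabola through the three points bracketing the discrete
minimum; a minimum on a scan endpoint is reported as "no minimum".

## Parameter fitting

`grid_fit()` reproduces the two-stage grid-search protocol: stage one
evaluates exhaustively `E` in 0.10-0.50, `R0` in 1.50-4.55 and `C` in
0.05-2.00 at 0.05 intervals (22,320 combinations); stage two refines the
winner by +/- 0.05 at 0.01 intervals, run once. The objective is the
mean over curves of the rmsd between the model curve (base score plus
CH-pi at unit weighting) and the reference, restricted to each curve's
fit range - from the first scan point where the reference energy is
negative (no interpolation) out to 6.0 angstrom, because the soft
quadratic repulsion of the base score cannot follow a quantum-mechanical
repulsive wall. Ties resolve to the lexicographically smallest
`(E, R0, C)`. The hydrogen-independent parameters are fitted against the
vertex-down family only (`fit_h_independent()` insists on curves A, D
and E), since the carbon-only form coincides with the angular form
exactly when the interacting hydrogen has unit angular factor.

No quantum-mechanical reference energies are shipped: the package's
default test path generates reference curves *synthetically* from known
parameter triples (`synth_reference_curves()`, labeled synthetic) and
demonstrates parameter recovery - exact in the noiseless case, `R0`
within 0.1 angstrom under 0.05 kcal/mol gaussian noise. Fitting against
real reference data is a user-supplied-input path through the same
functions (or `chpi fit` on TSV curve files).

## Torsion grid search

`best_rotamer()` enumerates one or two rotatable bonds on a 3-degree
grid (120^n conformations), discards rotamers with intramolecular
clashes (inclusive thresholds 2.0 angstrom heavy-heavy, 1.75
heavy-hydrogen, 1.40 hydrogen-hydrogen; 1-2 and 1-3 pairs exempt, 1-4
pairs checked), scores the survivors with the combined score and returns
the most negative total. Only receptor-ligand interaction energy is
scored - receptor-internal terms are not evaluated, so a side-chain
rotation that sacrifices an intra-receptor contact is invisible to the
search, a known limitation of this class of scoring. The rmsd to the
reference pose is computed over the moving-set heavy atoms in the fixed
frame without re-superposition, and exact score ties go to the first
angle tuple in grid order.

## Synthetic data

`make_synthetic_site()` builds a receptor of isolated PHE-like ring
fragments and a methane-probe ligand posed to realize requested
descriptor values (H-centroid distance, tilt), returning the
ground-truth geometry. It emulates the *geometry* of mined binding-site
contacts - tunable distance and tilt distributions against template
aromatic rings - but none of the context of real structures: no packing,
no competing polar contacts, no coordinate noise, no alternate
conformations, and probes instead of real ligands. Tests that pass on
these fixtures therefore establish the correctness of the detection
geometry, filters and bookkeeping, not mining performance on the PDB;
the large-scale mining tallies and docking benchmark campaigns that
motivated the method require external structure sets and a stochastic
search engine, and are out of scope here.

## Numerical choices and edge cases

* Hydrogen placement: missing aliphatic hydrogens are built at ideal
  tetrahedral geometry with a 1.09 angstrom C-H bond (`add_aliphatic_hydrogens()`);
  methyl rotors are staggered against the heaviest vicinal substituent.
  Existing hydrogens are never moved and completion is idempotent.
* Bond inference without CONECT records is by distance (1.9 angstrom
  heavy-heavy, 2.2 with sulfur, 1.2 hydrogen-heavy), which reproduces
  template connectivity for the standard residues; aromatic rings of
  PHE/TYR/HIS/TRP are additionally recognized by name templates, with
  the tryptophan indole treated as two independent rings, each with its
  own centroid.
* Ligand rings are 5- or 6-cycles of C/N that are coplanar within 0.2
  angstrom maximum deviation (a chair cyclohexane fails).
* theta2 is reported folded to [0, 90] degrees; the energy uses the
  directed angle so that away-pointing hydrogens drop out.
* omega uses the nearest ring atom and the nearer of its two ring
  neighbors, keeping the edge a real ring bond and the dihedral defined
  for symmetric axial poses.
* The B-factor filter averages per residue; the ligand counts as a
  single residue.
* The CH-pi term shares the base score's 8 angstrom cutoff so one
  neighbor list serves both.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
fixtures chosen to keep a full run at desk scale: dimer scans use the 22-
and 13/15-point grids above, detection oracles use up to 100 constructed
contacts, fitting recoveries run the full 22,320-point stage-1 box over
six 22-point curves, and rotamer searches use single-bond (120-rotamer)
cases with a 14,400-row enumeration checked for counting only.
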