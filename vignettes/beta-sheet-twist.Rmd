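---
title: "Why beta-strands twist to the right: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why beta-strands twist to the right: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betatwist)
```

## The question and the model

Virtually all beta-sheets, viewed along their strands, twist to the
right. `betatwist` implements a steric account of that bias and the
machinery to test it on idealized and real structures. The account has
two halves:

1. **A classification rule.** A residue's local twist is read off the
   backbone dihedrals: the wrapped sum `phi + psi` (reduced modulo 360
   into `(-180, 180]`) is zero on the diagonal of the Ramachandran
   torus, positive for a locally right-handed (clockwise, viewed from
   the N- toward the C-terminus) twist, and negative for a left-handed
   one. Sums at 0 or at the identified pair 180/-180 carry no twist;
   near +-180 the chain is no longer a realistic strand and the label
   is `none` with a `non_beta` flag.

2. **A steric mechanism.** In the fully extended chain two contacts are
   compressed below their Bondi hard-sphere distances: each carbonyl
   oxygen against the beta hydrogens of the *following* residue
   (O...H, radii 1.5 + 1.2 = 2.7 A) and each amide hydrogen against
   the side chain of the *preceding* residue (H...H, 1.2 + 1.2 =
   2.4 A). The first contact is relieved by rotating `phi` clockwise
   and re-limited by the own amide group; the second is relieved by
   rotating `psi` counter-clockwise and re-limited by the own carbonyl
   oxygen. Because the carbonyl group is bulkier than the amide, the
   `phi` rotation dominates, pushing `phi + psi` above the diagonal:
   a right-handed twist. Glycine has no side chain, neither contact
   exists, and polyglycine sheets stay flat — the package's polyglycine
   builds show zero side-chain clash categories.

The four contacts are named `CB_O_prev` (initiates `phi`),
`CB_HN_same` (limits `phi`), `CB_HN_next` (initiates `psi`) and
`CB_O_same` (limits `psi`), where the "side chain" is CB plus its
attached hydrogens. `clash_scan()` rebuilds the peptide along a
dihedral path and shows each rotation strictly opening its initiating
contact while strictly closing its limiting one.

## Building peptides from internal coordinates

`build_peptide()` places every atom by chain extension from three
predecessors (bond length, bond angle, torsion), so any conformation is
constructed exactly rather than optimized. Measuring a specified
dihedral on the output recovers it to 1e-6 degrees, which the tests
assert.

The geometry table uses standard single-conformer protein values:
N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231, CA-CB 1.530, N-H 1.010,
C-H 1.090 A; angles N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7,
CA-C-O 120.8 degrees, tetrahedral 109.5 elsewhere. Two choices deserve
a note:

* **The amide nitrogen is sp2.** The amide hydrogen is placed in the
  peptide plane, trans to the carbonyl oxygen, with C-N-H 119.2
  degrees. A tetrahedral default there would contradict peptide-bond
  planarity.
* **The methyl is staggered** (`chi1 = 60`, i.e. beta-H torsions at
  +60/180/-60 from N-CA-CB-H). A rigid-rotor force-field relaxation of
  the side-chain hydrogens against the fixed extended backbone ends in
  essentially the same staggered rotamer, so the deterministic
  staggered default stands in for side-chain optimization without
  loss.

Chirality is fixed to L-amino acids (the improper torsion C-N-CA-CB
comes out near -122 degrees); the D mirror is reachable only by
`mirror_structure()`, which the mirror-symmetry tests use. Termini are
completed as NH2 and C(=O)OH and excluded from the clash categories.
Alanine and glycine are exact; any other residue letter gets an
alanine-like CB stub, which is enough for the CB-centric clash scheme
but not for rotamer-dependent side-chain contacts.

With this table the extended tri-alanine shows the O...H-beta contact
at 2.20 A (0.50 A inside the 2.7 A Bondi sum) and the amide-H contact
at 2.08 A (0.32 A inside 2.4 A). A force-field-relaxed reference
yields the same contacts dilated by roughly 0.1-0.3 A — force fields
of the MMFF family use a visibly longer amide C-N bond (about 1.38 A
against the crystallographic 1.329 A used here) — so these two
distances sit near the lower edge of their published bands. The
idealized strand at `(phi, psi) = (-139, +135)` has an axial repeat
`Ca(i)...Ca(i+2)` of 6.93 A, inside the canonical 6.5-7.0 A band,
while the all-trans chain exceeds 7.0 A, being the longest possible
conformation (asserted against 1000 random conformations).

## Quantifying twist and bend geometrically

The classification rule is about dihedrals; to check it against actual
geometry, `peptide_plane_twist()` fits a least-squares plane through
each peptide unit (CA, C, O, N', H', CA') and measures the signed
rotation between successive plane normals about the local chain
direction. Two conventions had to be decided:

* The extended chain is a two-fold screw: successive peptide units flip
  their local orientation, so the raw inter-normal angle is offset by
  180 degrees from the twist proper. The reported twist subtracts that
  structural half-turn, making the all-trans chain measure 0.
* The sign is positive for clockwise rotation viewed from the N- toward
  the C-terminus, matching the handedness rule.

So defined, the plane twist is not merely sign-consistent with the
wrapped sum: across the sampled beta region the two agree in sign in
every case more than 10 degrees off the diagonal (the calibration test
requires at least 95%) and correlate at r > 0.99.

`bend_angle()` follows a separate definition: 180 degrees minus the
angle at the middle of three consecutive peptide-bond (C-N) midpoints.
One consequence of exact ideal geometry is worth knowing: because the
backbone angles CA-C-N (116.2) and C-N-CA (121.7) differ, those
midpoints of the extended chain do not lie exactly on the screw axis,
and the all-trans bend measures about 5 degrees rather than 0. The
bend of a uniform conformation is uniform along the chain, which is
what the tests pin down.

## The beta-region sampler

`sample_beta_dihedrals()` draws uniformly from the wrapped rectangle
`phi` in [160, -70] crossing +-180 and `psi` in [80, -160] crossing
+-180 — the broad beta region of the Ramachandran plot. It emulates
*where* beta residues live, not their empirical density: real strands
cluster above the diagonal more strongly than a uniform draw, so the
sampled right-hand share (about 54% of the box) understates the bias
in real sheets. Passing tests on sampled conformations therefore show
that the rules and the geometry are consistent over the whole region,
not that the package reproduces database statistics. Draws are
seed-reproducible and leave the caller's RNG state untouched.

## Numerical choices

* Angles are reported in `(-180, 180]`, with 180 the canonical
  representative of the identified pair 180/-180.
* Collinearity in torsion computation is declared when a cross-product
  norm falls below 1e-9 (in A^2) and raises a degenerate-geometry
  error rather than returning noise.
* The `none` band of the classifier is 1e-6 degrees by default and
  configurable; the strict inequalities of the interval rule leave
  exact multiples of 180 unclassified, which map to `none`.
* Nonbonded pairs are those three or more covalent bonds apart; 1-2
  and 1-3 distances are fixed by the geometry table and would swamp
  any report. A consequence: without hydrogens the same-residue amide
  category has no admissible pair (CB...N is 1-3), so on heavy-atom
  structures that category is dropped rather than faked.
* Clash flagging uses a strict inequality: a distance exactly equal to
  the radii sum is not a clash.
* Amide groups are represented by their hydrogen when present (the
  nitrogen is the heavy-atom fallback for crystal structures read
  without hydrogens). This keeps the scan distances strictly monotone,
  which is the property the mechanism argument needs.
* PDB serialization is deterministic; write -> read -> write is
  byte-identical, and coordinates round-trip at the format's 1e-3 A
  precision.

## Problem sizes

The shipped analyses and tests use tripeptides to octapeptides, 1000
random conformations for the maximality property, a 1-degree grid
(719 points) for the interval-rule equivalence, and 10000 sampled
dihedral pairs for region statistics; each script finishes in seconds.

## Known limitations

* Side chains beyond CB are stubs; contacts involving gamma atoms and
  beyond appear only as `other` records, and rotamer-dependent
  distances (e.g. between bulky second-next side chains) are out of
  scope.
* No energies: hard-sphere overlap only, no Lennard-Jones, no
  hydrogen-bond model, no interstrand analysis.
* PDB reading covers single-model ATOM/SHEET records; mmCIF, insertion
  codes, altloc beyond highest-occupancy selection and heteroatoms are
  not supported.
* Strand-level aggregation nets the sign of the mean wrapped sum
  (majority counts are reported alongside); the twist angle *between*
  neighbouring strands of a sheet is not computed, only the per-blade
  propeller arithmetic `end_to_end / (n_strands - 1)`.
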