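---
title: "Detecting collective lobe motion in atomic-resolution crystal structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting collective lobe motion in atomic-resolution crystal structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lobedyn)
```

## The problem

Many enzymes -- the pancreatic ribonucleases are the canonical family --
are bilobed: two lobes founded on beta-sheets flank the active-site
cleft, and a pincer-like "breathing" motion of the lobes opens and
closes that cleft in step with the catalytic cycle.  A single crystal
structure is a static snapshot, but at atomic resolution (better than
about 1.2 Å) three independent kinds of evidence for collective motion
become available, and `lobedyn` computes all three so they can be
compared residue by residue:

1. **Conformational differences between related structures.**
   Superposing two conformations (e.g. the same protein at room
   temperature and at 100 K, or with and without a ligand) gives a
   per-residue displacement field; a difference distance matrix (DDM)
   detects the same motion without any superposition at all.
2. **Anisotropic displacement parameters (ADPs).**  Atomic-resolution
   refinement assigns each atom a symmetric 3x3 tensor U (Å²) of
   mean-square positional fluctuations.  Its eigenvectors are the
   principal axes of motion; strongly anisotropic atoms point along
   the direction they prefer to move.
3. **Elastic-network normal modes.**  An anisotropic network model
   (ANM) built from the C-alpha coordinates alone predicts the
   lowest-frequency collective modes intrinsic to the fold.

When the displacement field from (1), the principal axes from (2) and
a low-frequency mode from (3) all describe the same inter-lobe
counter-motion, the case that the motion is real and intrinsic is far
stronger than any one analysis could make it.

## Models and conventions

### Superposition and displacement fields

`superpose()` computes the least-squares optimal proper rigid
transform (Kabsch, via SVD with the determinant correction; no
reflections) of a *fitting* atom subset, then reports displacement
vectors `reference − transformed mobile` over a possibly different
*reporting* subset.  Fitting on a rigid core (here the lobe-1
beta-sheet, "V1") and reporting all C-alpha atoms is the standard way
to display how everything else moves relative to that core.  Atoms
are paired by (chain, residue number, insertion code, atom name);
sequence alignment is out of scope.  "Global" alignment means all
pairable C-alpha atoms.  Degenerate fits (fewer than 3 pairs, or
collinear subsets) are errors, not warnings.

Mode/displacement overlap comparisons always use the *global*-fit
field: a subset fit leaves an arbitrary net rigid-body component in
the displacements, and the mode basis -- orthogonal to the rigid-body
space by construction -- cannot represent it, so overlaps against a
subset-fit field systematically understate agreement.

### Difference distance matrices

`difference_distance()` reports `d_B(i,j) − d_A(i,j)` over paired
C-alpha atoms.  The matrix is symmetric, zero on the diagonal and
exactly invariant to rigid motion of either input, which is its whole
point: a uniformly negative inter-lobe block is the
superposition-free signature of the lobes approaching each other.
Residues modelled in only one structure are dropped (intersection)
and listed in the output header.

### ADP analysis

For each atom carrying a U tensor: `b_eq(U) = (8π²/3)·trace(U)`;
eigenvalues λ₁ ≥ λ₂ ≥ λ₃ are the mean-square fluctuations along the
principal axes; the anisotropy is `A = λ₃/λ₁` (1 = isotropic sphere,
small = elongated ellipsoid).  Conventions that matter:

* eigenvalues in (−1e-8, 0] are clamped to 0, because deposited
  tensors can be marginally non-positive after ANISOU integer
  rounding; significantly negative eigenvalues are an error;
* atoms without ANISOU records are *excluded* from anisotropy
  statistics rather than treated as A = 1, which would dilute the
  distribution toward isotropy; the excluded count is reported;
* `select_anisotropic()` flags atoms with `A < mean(A) − k·sd(A)`
  (strict inequality, default k = 0.5, sample SD).  Low A means
  directional motion, so the selection keeps the atoms whose
  ellipsoids are the most elongated;
* for residues with alternate conformers, the highest-occupancy
  conformer represents the residue (ties broken by altloc
  lexicographic order, so the result is deterministic).

### ANM normal modes

`build_hessian()` connects C-alpha atoms within a cutoff `r_c`
(default 15 Å) by uniform springs (γ, default 1; a pure scale on the
eigenvalues).  The off-diagonal 3x3 block for a contact is
`−(γ/r²)·(r ⊗ r)` and diagonal blocks enforce the zero row-sum, so
the Hessian annihilates rigid translations and rotations exactly: a
connected, non-collinear network has exactly six zero-frequency
modes, and the first interesting mode is mode 7.  Trivial modes are
detected scale-freely (`λ < 1e-8 · λ_max`).  A disconnected network
is a warning and keeps its honest (> 6) trivial count rather than
being silently renumbered.

Eigenvector signs are arbitrary, so every reported mode passes
through `phase_orient()`, which picks the sign whose small-amplitude
displacement *decreases* the radius of gyration (the "compaction
phase").  The sign test is the analytic derivative
`d(Rg²)/dε ∝ Σ (xᵢ−x̄)·(vᵢ−v̄)`; a pure twist (derivative ≈ 0) falls
back to a deterministic convention and is flagged.

### Scalar metrics

* `radius_of_gyration()` is mass-weighted with standard IUPAC atomic
  weights keyed by the element column (older files with blank
  elements fall back to atom-name heuristics for hydrogen
  detection).  Structures should first pass `strip_for_geometry()`,
  which removes hydrogens, waters and non-polymer solutes, keeps one
  highest-occupancy conformer per atom, and *retains* covalently
  linked nonstandard residues (an N-terminal pyroglutamate carries a
  peptide backbone and belongs to the chain).
* `omega_dihedrals()` uses the IUPAC sign convention for
  CA(i−1)–C(i−1)–N(i)–CA(i), assigns the bond to the C-terminal
  residue i, and reports in [0°, 360°) so that strained *trans*
  peptides read as, say, 192.1° rather than −167.9°.  Bonds with
  C···N beyond 2.5 Å are chain breaks and are skipped.
* the active-site cleft width is an atom-pair distance (by default
  the main-chain N atoms of residues 35 and 98, the standard metric
  for this fold).

## The synthetic-data generator: what it emulates

No structure can be downloaded at test time, so the package ships
generators whose outputs have exactly the features the analyses
assume.

`make_two_lobe()` builds a V-shaped toy: two uniform balls of
C-alpha nodes (radius 3.5 Å) at the tips of 16 Å arms opened 100°
apart, joined by thin neck plates (node pairs at z = ±2 Å) meeting at
a hinge.  Three geometric decisions do real work:

* the lobe centres sit 24.5 Å apart, so at the 15 Å cutoff the lobes
  interact only *through the neck* -- the hinge, not direct lobe-lobe
  springs, controls the soft modes;
* the neck's vertical spread stiffens out-of-plane bending and
  torsion, leaving the in-plane pincer closing as the softest
  deformation.  Empirically mode 7 of the default toy is that pincer
  (overlap ≈ 0.97 with the hinge-closure field, spectral gap
  λ₇ ≈ 0.008 vs λ₈ ≈ 0.04), and this was verified across seeds
  before the tests were frozen;
* `close_hinge()` rotates the whole B side about the hinge z-axis.
  A rotation about that axis preserves every node's cylindrical
  radius and height while strictly reducing every cross-lobe
  azimuthal separation, so *all* inter-lobe distances shrink -- the
  all-negative DDM block is guaranteed by construction, not by luck.

`make_conformer_pair()` displaces coordinates along a (unit-norm)
mode by a chosen amplitude, giving pairs whose generating deformation
is known exactly.  `make_synthetic_adps()` plants
`U = R·diag(s, g·s, ρ·s)·Rᵀ` with the major axis along a supplied
field and `g ~ U(ρ, 1)`, so the recovered anisotropy is exactly ρ.

What the toy does *not* emulate: real bond geometry, side chains,
crystal-packing restraints, sequence, or refinement noise.  A green
synthetic test therefore establishes that the *algorithms* are
correct (signs, conventions, invariances, recoveries), not that any
particular protein behaves a particular way -- for that the
reproduction tests run on real deposited entries when those files
are present under `inst/extdata/pdb/` (the build environment of this
package had no network route to the PDB archive, so those tests
report their absence as explicit failures rather than silently
passing).

## Numerical choices

* ANISOU values are stored in files as U·10⁴; conversion happens at
  parse time and writing rounds to integers per the format.  The
  quantisation perturbs a planted anisotropy by roughly
  `1.5e-4·(1+ρ)/s` (per-entry rounding ≤ 5e-5, Weyl bound on the
  eigenvalues), so the default planting scale is s = 0.5 Å²
  (B_eq ≈ 25–35 Å², the upper experimental range) and the round-trip
  recovery test runs at s = 2 Å², where the bound guarantees
  |A − ρ| ≤ 1e-4.
* Superposition optimality is tested against a brute-force 10° Euler
  grid on small clouds; the SVD solution must never be worse.
* All generator randomness is seeded per call (`with_seed`), restores
  the caller's RNG state, and never touches global options; fixed
  seeds give byte-identical PDB output.
* Report precision follows the conventions of the field's printed
  tables: distances and RMSDs to 2 decimals, Rg to 3, anisotropy
  thresholds to 4.

## Worked example

```{r}
set.seed(0)
open_s  <- make_two_lobe(seed = 1)
open_s  <- make_synthetic_adps(open_s, ratio = 0.4, scale = 0.3, seed = 2)
model   <- build_hessian(coords(open_s))
dec     <- diagonalize(model)
mode7   <- phase_orient(dec$modes[[1]], model)
closed  <- make_conformer_pair(open_s, mode7, amplitude = 0.8)

ref <- tempfile(fileext = ".pdb"); mob <- tempfile(fileext = ".pdb")
write_pdb(open_s, ref); write_pdb(closed, mob)

cfg <- analysis_config(
  ref, mob,
  selections = list(V1 = list(c("A", 7, 26)), V2 = list(c("A", 31, 50)),
                    segment_I = list(c("A", 31, 40)),
                    segment_II = list(c("A", 41, 50))),
  cleft = c("A:10:CA", "A:35:CA"))
report <- run_report(cfg)
report$overlaps
```

The overlap table identifies mode 7 as the generating deformation;
on real structure pairs the same table quantifies how much of the
observed conformational change each intrinsic mode explains.

## Known limitations

* PDB format only (fixed columns, first model); mmCIF is not read.
* Pairing is by residue numbering, so entries renumbered relative to
  each other must be renumbered before comparison.
* The ANM uses a uniform spring constant; distance-weighted or
  residue-specific variants are out of scope, as are TLS
  decomposition of ADPs and solvent-excluded volume.
* Eigenvalue units are arbitrary (γ is arbitrary), so only mode
  shapes, orderings and ratios are meaningful -- never absolute
  frequencies.
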