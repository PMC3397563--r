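# lobedyn

Comparative structural dynamics of bilobed proteins from
atomic-resolution crystal structures.

Many enzymes of the pancreatic-ribonuclease fold are bilobed: two
lobes founded on beta-sheets flank the active-site cleft, and a
pincer-like "breathing" counter-motion of the lobes is thought to
accompany catalysis.  `lobedyn` implements the three independent
lines of evidence by which such collective motion is detected from
crystal structures, plus the plumbing to run them end to end:

* **Structure I/O** — fixed-column PDB reading/writing including
  ANISOU (anisotropic displacement) records, alternate conformers,
  unit cells; deterministic atom selection and a
  `strip_for_geometry()` step (drop hydrogens, waters, solutes; one
  conformer per atom; keep chain-linked nonstandard residues such as
  pyroglutamate).
* **Geometry** — least-squares rigid superposition (Kabsch/SVD, no
  reflections) with per-atom displacement fields
  (`reference − transformed mobile`), mass-weighted radius of
  gyration, atom and atom-to-group distances (cleft width), and
  omega peptide dihedrals reported in [0°, 360°).
* **Difference distance matrices** — superposition-free detection of
  inter-lobe motion: entry (i, j) is the change in the
  Cα(i)–Cα(j) distance between two conformations; an all-negative
  inter-lobe block means the lobes approach each other.
* **ADP analysis** — equivalent isotropic B-factor
  `B_eq = (8π²/3)·tr(U)`, tensor eigendecomposition, anisotropy
  `A = λ_min/λ_max`, and outlier selection
  `A < mean(A) − k·sd(A)` with principal-axis annotation.
* **ANM normal modes** — Cα elastic network with uniform springs
  within a cutoff (default 15 Å): Hessian with exact rigid-body null
  space, ascending spectrum (six trivial modes; the first interesting
  mode of a connected network is mode 7), per-residue square
  fluctuations, compaction-phase orientation, and cosine overlap of
  modes with observed displacement fields.
* **Synthetic data** — generators for two-lobe toy structures with a
  soft hinge, conformer pairs displaced along known modes, and
  planted anisotropic U tensors, so the whole pipeline is testable
  offline.
* **Pipeline + CLI** — `run_report()` aggregates everything into
  TSV tables and a log; `inst/cli/lobedyn.R` exposes `align`,
  `measure`, `ddm`, `adp`, `anm`, `synth` and `report` subcommands.

## Worked example

Build a two-lobe toy, displace it along its softest mode, and let the
pipeline recover the motion from the "crystal structures" alone:

```r
library(lobedyn)

open_s <- make_two_lobe(seed = 1)                      # 50 CA nodes
open_s <- make_synthetic_adps(open_s, ratio = 0.4, scale = 0.3, seed = 2)
model  <- build_hessian(coords(open_s))                # cutoff 15 A
dec    <- diagonalize(model)
mode7  <- phase_orient(dec$modes[[1]], model)          # compaction phase
closed <- make_conformer_pair(open_s, mode7, amplitude = 0.8)

ref <- tempfile(fileext = ".pdb"); mob <- tempfile(fileext = ".pdb")
write_pdb(open_s, ref); write_pdb(closed, mob)

cfg <- analysis_config(
  ref, mob,
  selections = list(V1 = list(c("A", 7, 26)), V2 = list(c("A", 31, 50)),
                    segment_I = list(c("A", 31, 40)),
                    segment_II = list(c("A", 41, 50))),
  cleft = c("A:10:CA", "A:35:CA"))
report <- run_report(cfg)
```

The run log (also written to `run.log` when `out_dir` is set) prints:

```
Rg: reference 11.668 A, mobile 11.591 A
global CA RMSD 0.11 A over 50 atoms; V1-fit CA displacements 0.00-0.51 A
DDM: mean -0.0775 A, 65.3% of pairs negative
cleft width: reference 21.77 A, mobile 21.55 A
ADP: 50 CA records, mean B_eq 16.4 A^2, mean A 0.400 +/- 0.000, threshold 0.4000, 16 selected
ANM: 6 trivial modes; nontrivial eigenvalues 0.007623, 0.04209, 0.08764, 0.1609, 0.6162, 1.06
```

Reading it: the mobile conformer is more compact (smaller Rg, mostly
negative DDM, narrower cleft) — the lobes moved toward each other —
and the planted anisotropy (0.4 at every node, hence SD 0 and a
degenerate selection) is recovered exactly.  The overlap table pins
the deformation on the generating mode:

```r
report$overlaps
#>   mode eigenvalue overlap_signed overlap_absolute
#> 1    7     0.0076         -1e+00            1e+00
#> 2    8     0.0421          1e-04            1e-04
#> 3    9     0.0876         -6e-04            6e-04
#> 4   10     0.1609         -2e-04            2e-04
#> 5   11     0.6162          0e+00            0e+00
#> 6   12     1.0598         -3e-04            3e-04
```

Mode 7 explains the observed displacement field completely
(|overlap| = 1; the sign is −1 because displacements are reported as
`reference − mobile`, i.e. the opening direction, while the mode is
oriented in its compaction phase).  On real structure pairs the same
table quantifies how much of a cryocooling- or ligand-induced
conformational change each intrinsic mode accounts for.

## Command line

```sh
Rscript inst/cli/lobedyn.R synth two-lobe --seed 1 --o toy.pdb
Rscript inst/cli/lobedyn.R measure --rgyr --omega toy.pdb
Rscript inst/cli/lobedyn.R anm toy.pdb --cutoff 15 --modes 6 --nmd toy.nmd
Rscript inst/cli/lobedyn.R ddm toy.pdb other.pdb --out ddm.tsv
Rscript inst/cli/lobedyn.R report --config analysis.yaml
```

## Documentation

`vignettes/lobe-dynamics.Rmd` describes the models, conventions
(omega sign and range, anisotropy selection, compaction-phase
orientation), the synthetic generator's geometry and what green
synthetic tests do and do not establish, and the numerical choices
(ANISOU quantisation bounds, trivial-mode tolerances).
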