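Package: lobedyn
Title: Comparative Structural Dynamics of Bilobed Proteins from
    Atomic-Resolution Crystal Structures
Version: 0.1.0
Authors@R:
    person("Structural Dynamics", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative structural-dynamics analysis of
    atomic-resolution protein crystal structures, with an emphasis on
    pincer-like ("breathing") motion of bilobed folds such as the
    pancreatic ribonucleases.  Reads and writes PDB-format coordinate
    files including anisotropic displacement (ANISOU) records and
    alternate conformers; performs least-squares rigid-body
    superposition with per-atom displacement fields; computes
    difference distance matrices, mass-weighted radii of gyration,
    omega peptide dihedrals and active-site cleft widths; analyses
    anisotropic displacement parameters (equivalent isotropic B,
    tensor eigendecomposition, anisotropy, outlier selection); and
    builds anisotropic-network-model (ANM) normal modes of a C-alpha
    elastic network, including mode/displacement overlap and
    compaction-phase orientation.  A synthetic-data module generates
    two-lobe toy structures, conformer pairs displaced along known
    modes, and structures with planted anisotropic U tensors, so the
    whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
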