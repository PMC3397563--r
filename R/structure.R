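# The coordinate container.
#
# Atoms are held in a single flat data.frame (one row per atom record,
# alternate conformers as separate rows), ordered as deposited.  This is
# the idiom used by the field's R structure packages: hierarchy
# (chain -> residue -> atom) is encoded in the (chain, resno, inscode)
# columns rather than in nested lists, which keeps selection and
# vectorised geometry cheap.

.atom_columns <- c("serial", "name", "altloc", "resname", "chain", "resno",
                   "inscode", "x", "y", "z", "occ", "b",
                   "u11", "u22", "u33", "u12", "u13", "u23",
                   "element", "hetero")

#' Construct a structure object
#'
#' @param atoms data.frame with one row per atom record and columns
#'   `serial`, `name`, `altloc`, `resname`, `chain`, `resno`, `inscode`,
#'   `x`, `y`, `z`, `occ`, `b`, `u11`..`u23` (anisotropic U in
#'   square Angstroms, `NA` when absent), `element`, `hetero`.
#' @param id character identifier (typically the PDB code or file stem).
#' @param unit_cell optional numeric vector
#'   `c(a, b, c, alpha, beta, gamma)` (Angstroms / degrees).
#' @param spacegroup optional Hermann-Mauguin symbol.
#' @return An object of class `pdb_structure`.
#' @export
pdb_structure <- function(atoms, id = "structure", unit_cell = NULL,
                          spacegroup = NULL) {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(.atom_columns, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, .atom_columns]
  if (nrow(atoms)) {
    if (any(atoms$occ < -1e-9 | atoms$occ > 1 + 1e-9))
      stop("occupancies must lie in [0, 1]")
    atoms$occ <- pmin(pmax(atoms$occ, 0), 1)
    if (any(atoms$b < 0, na.rm = TRUE))
      stop("isotropic B-factors must be non-negative")
  }
  if (!is.null(unit_cell)) {
    unit_cell <- as.numeric(unit_cell)
    if (length(unit_cell) != 6L || any(unit_cell[1:3] <= 0))
      stop("unit_cell must be c(a, b, c, alpha, beta, gamma) with positive lengths")
  }
  structure(list(id = id, atoms = atoms, unit_cell = unit_cell,
                 spacegroup = spacegroup),
            class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms
  nres <- nrow(unique(a[!a$hetero, c("chain", "resno", "inscode")]))
  cat(sprintf("<pdb_structure '%s': %d atom records, %d polymer residues, %d chain(s)%s>\n",
              x$id, nrow(a), nres, length(unique(a$chain)),
              if (any(!is.na(a$u11))) ", with ANISOU" else ""))
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param s `pdb_structure` or atom data.frame.
#' @return n x 3 numeric matrix (Angstroms).
#' @export
coords <- function(s) {
  a <- if (inherits(s, "pdb_structure")) s$atoms else s
  as.matrix(a[, c("x", "y", "z")])
}

#' Anisotropic U tensor of one atom row
#'
#' @param atom single-row atom data.frame.
#' @return symmetric 3x3 matrix in square Angstroms, or `NULL` if the
#'   atom carries no ANISOU record.
#' @export
u_tensor <- function(atom) {
  stopifnot(nrow(atom) == 1L)
  if (is.na(atom$u11)) return(NULL)
  matrix(c(atom$u11, atom$u12, atom$u13,
           atom$u12, atom$u22, atom$u23,
           atom$u13, atom$u23, atom$u33), 3L, 3L)
}

# Residue names treated as water.
.water_resnames <- c("HOH", "WAT", "DOD", "H2O")

#' Identify hydrogen (or deuterium) atoms
#'
#' Uses the element column when present; for records with a blank
#' element, falls back to the standard name heuristic (first alphabetic
#' character of the atom name after leading digits).
#' @noRd
is_hydrogen <- function(atoms) {
  el <- toupper(trimws(atoms$element))
  out <- el %in% c("H", "D")
  blank <- el == ""
  if (any(blank)) {
    nm <- toupper(trimws(atoms$name[blank]))
    nm <- sub("^[0-9]+", "", nm)
    out[blank] <- substr(nm, 1L, 1L) %in% c("H", "D")
  }
  out
}

#' Selection of atoms by residue range, atom name and conformer policy
#'
#' @param ranges `NULL` (all residues) or a list of ranges, each
#'   `c(chain, start, end)` (chain as character, bounds inclusive and
#'   coercible to integer).
#' @param atom_names `NULL` (all atoms) or character vector of atom
#'   names, e.g. `"CA"`.
#' @param altloc conformer policy: `"highest"` keeps, per
#'   (residue, atom name), the single highest-occupancy conformer (ties
#'   broken by altloc lexicographic order, 'A' first); `"all"` keeps
#'   every conformer; `"specific"` keeps blank plus `altloc_id`.
#' @param altloc_id conformer identifier used when
#'   `altloc = "specific"`.
#' @param include_hetero keep HETATM records (default `TRUE`; ranges
#'   match hetero residues too, which lets selections address ligands).
#' @return An object of class `atom_selection`.
#' @export
atom_selection <- function(ranges = NULL, atom_names = NULL,
                           altloc = c("highest", "all", "specific"),
                           altloc_id = "A", include_hetero = TRUE) {
  altloc <- match.arg(altloc)
  if (!is.null(ranges)) {
    if (!is.list(ranges)) ranges <- list(ranges)
    ranges <- lapply(ranges, function(r) {
      if (length(r) != 3L) stop("each range must be c(chain, start, end)")
      list(chain = as.character(r[[1L]]), start = as.integer(r[[2L]]),
           end = as.integer(r[[3L]]))
    })
  }
  structure(list(ranges = ranges, atom_names = atom_names, altloc = altloc,
                 altloc_id = altloc_id, include_hetero = include_hetero),
            class = "atom_selection")
}

#' Resolve a selection against a structure
#'
#' Returns the matching atom rows in structure order.  Under the
#' `"highest"` conformer policy exactly one row per
#' (chain, residue, atom name) survives.
#'
#' @param s `pdb_structure`.
#' @param sel `atom_selection`.
#' @return data.frame of atom rows (structure order preserved).
#' @export
resolve_selection <- function(s, sel) {
  stopifnot(inherits(s, "pdb_structure"), inherits(sel, "atom_selection"))
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!sel$include_hetero) keep <- keep & !a$hetero
  if (!is.null(sel$ranges)) {
    in_range <- rep(FALSE, nrow(a))
    for (r in sel$ranges) {
      if (!any(a$chain == r$chain))
        stop("selection references chain '", r$chain,
             "' absent from structure '", s$id, "'")
      in_range <- in_range |
        (a$chain == r$chain & a$resno >= r$start & a$resno <= r$end)
    }
    keep <- keep & in_range
  }
  if (!is.null(sel$atom_names))
    keep <- keep & trimws(a$name) %in% sel$atom_names
  if (sel$altloc == "specific")
    keep <- keep & (a$altloc == "" | a$altloc == sel$altloc_id)
  a <- a[keep, , drop = FALSE]
  if (sel$altloc == "highest" && nrow(a)) {
    key <- paste(a$chain, a$resno, a$inscode, trimws(a$name), sep = "\r")
    # stable pick: highest occupancy, ties to lexicographically first altloc
    ord <- order(key, -a$occ, a$altloc)
    first <- !duplicated(key[ord])
    picked <- sort(ord[first])          # restore structure order
    a <- a[picked, , drop = FALSE]
  }
  if (!nrow(a))
    stop("selection matches no atoms in structure '", s$id, "'")
  a
}

#' Reduce a structure to the atoms used for geometric metrics
#'
#' Removes hydrogen atoms, waters and non-polymer hetero groups
#' (solutes, ions), and keeps a single highest-occupancy conformer per
#' atom (occupancy reset to 1).  Covalently linked nonstandard chain
#' residues -- hetero residues that carry a peptide backbone, such as an
#' N-terminal pyroglutamate -- are retained.
#'
#' @param s `pdb_structure`.
#' @return A new `pdb_structure`.
#' @export
strip_for_geometry <- function(s) {
  stopifnot(inherits(s, "pdb_structure"))
  a <- s$atoms
  a <- a[!is_hydrogen(a), , drop = FALSE]
  a <- a[!(toupper(a$resname) %in% .water_resnames), , drop = FALSE]
  # polymer test per residue: standard ATOM residues always stay; a
  # hetero residue stays only if it has a peptide backbone (N, CA, C)
  rkey <- paste(a$chain, a$resno, a$inscode, sep = "\r")
  keep_res <- vapply(split(seq_len(nrow(a)), rkey), function(idx) {
    if (!all(a$hetero[idx])) return(TRUE)
    all(c("N", "CA", "C") %in% trimws(a$name[idx]))
  }, logical(1L))
  a <- a[keep_res[rkey], , drop = FALSE]
  if (nrow(a)) {
    key <- paste(rkey[keep_res[rkey]], trimws(a$name), sep = "\r")
    ord <- order(key, -a$occ, a$altloc)
    first <- !duplicated(key[ord])
    a <- a[sort(ord[first]), , drop = FALSE]
    a$occ <- 1
    a$altloc <- ""
  }
  pdb_structure(a, id = s$id, unit_cell = s$unit_cell,
                spacegroup = s$spacegroup)
}

#' Count non-hydrogen atom records by category
#'
#' Alternate conformers are included; hydrogens are excluded
#' explicitly (deposited files may carry riding hydrogens).
#'
#' @param s `pdb_structure`.
#' @return named integer vector: `protein`, `water`, `other_hetero`,
#'   `total`.
#' @export
count_atoms <- function(s) {
  a <- s$atoms[!is_hydrogen(s$atoms), , drop = FALSE]
  water <- toupper(a$resname) %in% .water_resnames
  rkey <- paste(a$chain, a$resno, a$inscode, sep = "\r")
  backbone <- vapply(split(seq_len(nrow(a)), rkey), function(idx) {
    all(c("N", "CA", "C") %in% trimws(a$name[idx]))
  }, logical(1L))
  polymer <- (!a$hetero | backbone[rkey]) & !water
  c(protein = sum(polymer), water = sum(water),
    other_hetero = sum(!polymer & !water), total = nrow(a))
}
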