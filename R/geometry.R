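# Rigid-body superposition and scalar geometric metrics.

#' Pair atoms of two structures by identity
#'
#' Atoms are paired by (chain, residue number, insertion code, atom
#' name) after resolving `sel` on each structure with its conformer
#' policy.
#' @noRd
pair_atoms <- function(a, b, sel, a_id = "A", b_id = "B", strict = TRUE) {
  ra <- resolve_selection(a, sel)
  rb <- resolve_selection(b, sel)
  key <- function(d) paste(d$chain, d$resno, d$inscode, trimws(d$name),
                           sep = "\r")
  ka <- key(ra); kb <- key(rb)
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("selection resolves to duplicate atom identities; ",
         "use a single-conformer altloc policy")
  common <- intersect(ka, kb)
  miss_a <- setdiff(kb, ka)
  miss_b <- setdiff(ka, kb)
  if (strict && (length(miss_a) || length(miss_b))) {
    label <- function(k) paste(gsub("\r", ":", k), collapse = ", ")
    stop("selection is not pairable between '", a_id, "' and '", b_id,
         "'; missing in ", a_id, ": [", label(utils::head(miss_a, 10L)),
         "]; missing in ", b_id, ": [", label(utils::head(miss_b, 10L)), "]")
  }
  if (!length(common)) stop("no atoms pairable between structures")
  ia <- match(common, ka)
  ib <- match(common, kb)
  ord <- order(ia)                     # keep first structure's order
  list(a = ra[ia[ord], , drop = FALSE], b = rb[ib[ord], , drop = FALSE],
       dropped = c(miss_a, miss_b))
}

#' Optimal rotation (Kabsch, SVD) for row-vector coordinates
#'
#' Returns R such that `(P - centroid(P)) %*% R + centroid(Q)`
#' minimises the RMSD to Q; proper rotation only (no reflection).
#' @noRd
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)                 # t(P) %*% Q, both pre-centred
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Check that a centred point set spans more than a line
#' @noRd
assert_not_collinear <- function(X, label) {
  sv <- svd(X, nu = 0L, nv = 0L)$d
  if (length(sv) < 2L || sv[2L] < 1e-8 * max(sv[1L], 1e-300))
    stop("degenerate fit: ", label, " atoms are collinear (or fewer than ",
         "3 distinct positions)")
}

#' Least-squares rigid-body superposition
#'
#' Superposes `mobile` onto `reference` using the atoms of `fit_sel`
#' (paired by chain, residue number, insertion code and atom name) and
#' reports RMSD plus per-atom displacement vectors over `report_sel`.
#' The transform is the global least-squares optimum over proper rigid
#' motions (Kabsch); displacement vectors are
#' `reference - transformed mobile`, expressed in the reference frame.
#'
#' @param mobile,reference `pdb_structure` objects.
#' @param fit_sel `atom_selection` used for the fit; must resolve to at
#'   least 3 non-collinear paired atoms.
#' @param report_sel `atom_selection` over which displacements and the
#'   reporting RMSD are computed (defaults to `fit_sel`).
#' @param strict error when the selection cannot be fully paired
#'   (`TRUE`, default) or silently use the pairable intersection
#'   (`FALSE`).
#' @return An object of class `superposition` with elements `rotation`
#'   (3x3, column-vector convention `x' = R x + t`), `translation`,
#'   `fit_rmsd`, `report_rmsd`, `displacements` (data.frame of paired
#'   report atoms with `dx`, `dy`, `dz`, `norm`), `n_fit`, `dropped`.
#' @export
superpose <- function(mobile, reference, fit_sel,
                      report_sel = fit_sel, strict = TRUE) {
  pr <- pair_atoms(mobile, reference, fit_sel,
                   a_id = mobile$id, b_id = reference$id, strict = strict)
  P <- coords(pr$a); Q <- coords(pr$b)
  if (nrow(P) < 3L) stop("degenerate fit: need at least 3 paired atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  assert_not_collinear(Pc, "fit (mobile)")
  assert_not_collinear(Qc, "fit (reference)")
  R <- kabsch_rotation(Pc, Qc)
  fit_dev <- Qc - Pc %*% R
  fit_rmsd <- sqrt(mean(rowSums(fit_dev^2)))

  rp <- pair_atoms(mobile, reference, report_sel,
                   a_id = mobile$id, b_id = reference$id, strict = strict)
  Pm <- sweep(coords(rp$a), 2L, cp) %*% R
  Pm <- sweep(Pm, 2L, cq, `+`)
  D <- coords(rp$b) - Pm
  disp <- data.frame(chain = rp$b$chain, resno = rp$b$resno,
                     inscode = rp$b$inscode, name = trimws(rp$b$name),
                     dx = D[, 1L], dy = D[, 2L], dz = D[, 3L],
                     norm = sqrt(rowSums(D^2)))
  structure(list(rotation = t(R),
                 translation = as.numeric(cq - t(R) %*% cp),
                 fit_rmsd = fit_rmsd,
                 report_rmsd = sqrt(mean(disp$norm^2)),
                 displacements = disp,
                 n_fit = nrow(P),
                 dropped = pr$dropped),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: %d fit atoms, fit RMSD %.3f A, report RMSD %.3f A>\n",
              x$n_fit, x$fit_rmsd, x$report_rmsd))
  invisible(x)
}

#' Mass-weighted radius of gyration
#'
#' `Rg = sqrt( sum m_i ||r_i - r_com||^2 / sum m_i )` with the
#' mass-weighted centre of mass and standard atomic weights keyed by
#' element.  The structure should normally have passed through
#' [strip_for_geometry()] first (hydrogens, waters and solutes removed,
#' one conformer per atom).
#'
#' @param s `pdb_structure` with at least one atom.
#' @return Radius of gyration in Angstroms.
#' @export
radius_of_gyration <- function(s) {
  stopifnot(inherits(s, "pdb_structure"))
  a <- s$atoms
  if (!nrow(a)) stop("cannot compute radius of gyration of an empty structure")
  m <- atomic_mass(a$element)
  X <- coords(a)
  com <- colSums(X * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(X, 2L, com)^2)) / sum(m))
}

#' Parse an atom specifier
#'
#' Accepts `"chain:resno:name"` strings (e.g. `"A:35:N"`) or lists with
#' elements `chain`, `resno`, `name` and optional `inscode`.
#' @noRd
parse_atom_spec <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 3L)
      stop("atom spec must be 'chain:resno:name', got '", spec, "'")
    spec <- list(chain = parts[1L], resno = as.integer(parts[2L]),
                 name = parts[3L])
  }
  if (is.null(spec$inscode)) spec$inscode <- ""
  spec
}

#' Look up one atom (highest-occupancy conformer)
#' @noRd
find_atom <- function(s, spec) {
  spec <- parse_atom_spec(spec)
  a <- s$atoms
  hit <- a$chain == spec$chain & a$resno == spec$resno &
    a$inscode == spec$inscode & trimws(a$name) == spec$name
  if (!any(hit))
    stop("atom not found: ", spec$chain, ":", spec$resno, ":", spec$name,
         " in structure '", s$id, "'")
  rows <- a[hit, , drop = FALSE]
  rows[order(-rows$occ, rows$altloc)[1L], , drop = FALSE]
}

#' Distance between two named atoms
#'
#' @param s `pdb_structure`.
#' @param a,b atom specifiers, `"chain:resno:name"` or
#'   `list(chain=, resno=, name=)`.  The highest-occupancy conformer is
#'   used.
#' @return Euclidean distance in Angstroms.
#' @export
atom_distance <- function(s, a, b) {
  ra <- find_atom(s, a)
  rb <- find_atom(s, b)
  sqrt(sum((coords(ra) - coords(rb))^2))
}

#' Minimum distance from one atom to a group
#'
#' @param s `pdb_structure`.
#' @param a atom specifier (as in [atom_distance()]).
#' @param group `atom_selection` resolving to at least one atom.
#' @return list with `distance` (Angstroms) and `atom` (the closest
#'   atom row; ties broken deterministically by serial number).
#' @export
min_distance_to_group <- function(s, a, group) {
  ra <- find_atom(s, a)
  g <- resolve_selection(s, group)
  d <- unname(sqrt(rowSums(sweep(coords(g), 2L, as.numeric(coords(ra)))^2)))
  best <- order(d, g$serial)[1L]
  list(distance = d[best], atom = g[best, , drop = FALSE])
}

#' Dihedral angle of four points, degrees in (-180, 180]
#' @noRd
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  # IUPAC sign: atan2((n1 x n2) . b2_hat, n1 . n2)
  atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)),
        sum(n1 * n2)) * 180 / pi
}

#' Omega peptide-bond dihedrals
#'
#' For consecutive residues i-1, i the omega torsion is
#' CA(i-1) - C(i-1) - N(i) - CA(i), assigned to residue i (the
#' C-terminal residue of the bond) and reported in [0, 360) degrees so
#' that strained trans peptides print as e.g. 192.1 rather than -167.9.
#' A bond whose C(i-1)...N(i) distance exceeds 2.5 Angstroms is
#' treated as a chain break and skipped.
#'
#' @param s `pdb_structure`.  The highest-occupancy conformer is used.
#' @return data.frame with `chain`, `resno` (residue i), `resname`,
#'   `omega` (degrees in [0, 360)).
#' @export
omega_dihedrals <- function(s) {
  stopifnot(inherits(s, "pdb_structure"))
  bb <- resolve_selection(s, atom_selection(atom_names = c("N", "CA", "C"),
                                            altloc = "highest"))
  rkey <- paste(bb$chain, bb$resno, bb$inscode, sep = "\r")
  res <- bb[!duplicated(rkey), c("chain", "resno", "inscode", "resname")]
  get_xyz <- function(i, nm) {
    hit <- which(rkey == paste(res$chain[i], res$resno[i], res$inscode[i],
                               sep = "\r") & trimws(bb$name) == nm)
    if (!length(hit)) return(NULL)
    as.numeric(coords(bb[hit[1L], , drop = FALSE]))
  }
  out <- list()
  for (i in seq_len(nrow(res))[-1L]) {
    if (res$chain[i] != res$chain[i - 1L]) next
    ca0 <- get_xyz(i - 1L, "CA"); c0 <- get_xyz(i - 1L, "C")
    n1 <- get_xyz(i, "N"); ca1 <- get_xyz(i, "CA")
    if (is.null(ca0) || is.null(c0) || is.null(n1) || is.null(ca1)) next
    if (sqrt(sum((n1 - c0)^2)) > 2.5) next   # chain break
    w <- dihedral4(ca0, c0, n1, ca1) %% 360
    out[[length(out) + 1L]] <- data.frame(
      chain = res$chain[i], resno = res$resno[i],
      resname = res$resname[i], omega = w)
  }
  if (!length(out))
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), omega = numeric()))
  do.call(rbind, out)
}
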