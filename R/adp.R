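# Anisotropic displacement parameter (ADP) analysis.
#
# At atomic resolution each atom's positional spread is refined as a
# symmetric 3x3 tensor U (square Angstroms).  Diagonalising U gives the
# three principal axes (eigenvectors) and their mean-square
# fluctuations (eigenvalues).  The anisotropy A = lambda_min /
# lambda_max is 1 for a perfect sphere and approaches 0 for a strongly
# elongated ellipsoid; the equivalent isotropic B-factor is
# B_eq = (8 pi^2 / 3) * trace(U).

#' Equivalent isotropic B-factor of a U tensor
#'
#' @param u symmetric 3x3 matrix, square Angstroms.
#' @return `(8 pi^2 / 3) * trace(u)` in square Angstroms.
#' @export
b_eq <- function(u) {
  stopifnot(is.matrix(u), all(dim(u) == 3L))
  if (max(abs(u - t(u))) > 1e-8 * max(abs(u), 1e-300))
    stop("U tensor is not symmetric")
  (8 * pi^2 / 3) * sum(diag(u))
}

#' Eigendecomposition of a U tensor
#'
#' Eigenvalues are returned in decreasing order; values in
#' (-1e-8, 0] are clamped to 0 (deposited tensors can be marginally
#' non-positive after ANISOU rounding).
#' @noRd
adp_eigen <- function(u) {
  if (max(abs(u - t(u))) > 1e-8 * max(abs(u), 1e-300))
    stop("U tensor is not symmetric")
  e <- eigen((u + t(u)) / 2, symmetric = TRUE)   # decreasing order
  lam <- e$values
  lam[lam > -1e-8 & lam <= 0] <- 0
  if (any(lam < 0))
    stop("U tensor has a significantly negative eigenvalue (",
         format(min(lam)), ")")
  list(values = lam, vectors = e$vectors)
}

#' Anisotropy of a U tensor
#'
#' @param u symmetric, positive-semidefinite 3x3 matrix.
#' @return `lambda_min / lambda_max` (dimensionless, in (0, 1] for a
#'   positive-definite tensor).
#' @export
anisotropy <- function(u) {
  stopifnot(is.matrix(u), all(dim(u) == 3L))
  e <- adp_eigen(u)
  if (e$values[1L] <= 0) stop("degenerate U tensor: largest eigenvalue <= 0")
  e$values[3L] / e$values[1L]
}

#' Per-atom ADP records for a structure
#'
#' Resolves the selection (highest-occupancy conformer), keeps atoms
#' that carry a U tensor, and computes B_eq, the eigenvalues, the
#' anisotropy and the largest principal axis for each.  Atoms without
#' ANISOU records are excluded from the table (not treated as
#' isotropic) and counted in the `n_excluded` attribute.
#'
#' @param s `pdb_structure`.
#' @param sel `atom_selection` (default: C-alpha atoms).
#' @return data.frame with columns `chain`, `resno`, `inscode`,
#'   `resname`, `name`, `b_iso` (the file's B column), `b_eq`,
#'   `lambda1` >= `lambda2` >= `lambda3`, `anisotropy`, `ax`, `ay`,
#'   `az` (unit principal axis of lambda1).
#' @export
adp_records <- function(s, sel = atom_selection(atom_names = "CA")) {
  a <- resolve_selection(s, sel)
  has_u <- !is.na(a$u11)
  n_excluded <- sum(!has_u)
  a <- a[has_u, , drop = FALSE]
  if (!nrow(a)) stop("no atoms in the selection carry ANISOU records")
  rec <- lapply(seq_len(nrow(a)), function(i) {
    u <- u_tensor(a[i, , drop = FALSE])
    e <- adp_eigen(u)
    if (e$values[1L] <= 0)
      stop("degenerate U tensor on atom serial ", a$serial[i])
    data.frame(chain = a$chain[i], resno = a$resno[i],
               inscode = a$inscode[i], resname = a$resname[i],
               name = trimws(a$name[i]), b_iso = a$b[i],
               b_eq = b_eq(u),
               lambda1 = e$values[1L], lambda2 = e$values[2L],
               lambda3 = e$values[3L],
               anisotropy = e$values[3L] / e$values[1L],
               ax = e$vectors[1L, 1L], ay = e$vectors[2L, 1L],
               az = e$vectors[3L, 1L])
  })
  out <- do.call(rbind, rec)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Select strongly anisotropic atoms
#'
#' Flags atoms whose anisotropy lies below the mean by at least `k`
#' standard deviations: threshold `mean(A) - k * sd(A)`, selection
#' `A < threshold` (strict).  Small A means an elongated ellipsoid, so
#' these are the atoms with the most directional motion.  Each selected
#' atom is annotated with its largest principal axis scaled by
#' lambda1.
#'
#' @param records data.frame from [adp_records()] (>= 2 rows).
#' @param k threshold offset in standard deviations (default 0.5).
#' @param sd_type `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @return list with `threshold`, `mean`, `sd`, and `selected` (the
#'   selected record rows plus scaled-axis columns `sx`, `sy`, `sz`).
#' @export
select_anisotropic <- function(records, k = 0.5,
                               sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (nrow(records) < 2L) stop("need at least 2 ADP records")
  A <- records$anisotropy
  m <- mean(A)
  s <- stats::sd(A)
  if (sd_type == "population") s <- s * sqrt((length(A) - 1) / length(A))
  thr <- m - k * s
  sel <- records[A < thr, , drop = FALSE]
  if (nrow(sel)) {
    sel$sx <- sel$ax * sel$lambda1
    sel$sy <- sel$ay * sel$lambda1
    sel$sz <- sel$az * sel$lambda1
  }
  list(threshold = thr, mean = m, sd = s, selected = sel)
}
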