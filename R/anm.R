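# Anisotropic network model (ANM) normal modes.
#
# The protein is reduced to its C-alpha atoms, connected by uniform
# Hookean springs (constant gamma) whenever two atoms lie within a
# cutoff distance r_c (default 15 Angstroms).  The 3N x 3N Hessian has
# off-diagonal 3x3 blocks
#     H_ij = -(gamma / r_ij^2) * (r_ij %o% r_ij)      for r_ij <= r_c
# and diagonal blocks H_ii = -sum_{j != i} H_ij.  Its eigenvectors are
# the normal modes; a connected, non-collinear network has exactly six
# zero-frequency (rigid-body) modes, so the first interesting mode of a
# protein is conventionally "mode 7".

#' Build an ANM model from coordinates
#'
#' @param x N x 3 coordinate matrix (Angstroms), or a `pdb_structure`
#'   (its highest-occupancy C-alpha atoms are used; nonstandard chain
#'   residues with a CA, such as an N-terminal pyroglutamate, are
#'   included).
#' @param gamma uniform spring constant (arbitrary units, default 1).
#' @param cutoff interaction cutoff r_c in Angstroms (default 15).
#' @return An object of class `anm_model`: `coords`, `gamma`, `cutoff`,
#'   `hessian` (3N x 3N), `n_components` (connected components of the
#'   contact graph; a warning is issued when > 1).
#' @export
build_hessian <- function(x, gamma = 1, cutoff = 15) {
  if (inherits(x, "pdb_structure"))
    x <- coords(resolve_selection(x, atom_selection(atom_names = "CA")))
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3L, cutoff > 0)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 nodes")
  d <- as.matrix(stats::dist(x))
  contact <- d <= cutoff
  diag(contact) <- FALSE
  if (any(contact & d < 1e-6))
    stop("duplicate node coordinates within the cutoff (zero-length spring)")
  H <- matrix(0, 3L * n, 3L * n)
  pairs <- which(contact & upper.tri(contact), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    rij <- x[j, ] - x[i, ]
    blk <- -(gamma / sum(rij^2)) * tcrossprod(rij)
    ii <- (3L * i - 2L):(3L * i); jj <- (3L * j - 2L):(3L * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  n_components <- graph_components(contact)
  if (n_components > 1L)
    warning("contact network is disconnected (", n_components,
            " components); more than 6 trivial modes will appear")
  structure(list(coords = x, gamma = gamma, cutoff = cutoff, hessian = H,
                 n_components = n_components),
            class = "anm_model")
}

#' Connected components of an adjacency matrix (BFS)
#' @noRd
graph_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  comp <- 0L
  for (start in seq_len(n)) {
    if (seen[start]) next
    comp <- comp + 1L
    frontier <- start
    seen[start] <- TRUE
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nb] <- TRUE
      frontier <- nb
    }
  }
  comp
}

#' @export
print.anm_model <- function(x, ...) {
  cat(sprintf("<anm_model: %d nodes, gamma %g, cutoff %g A%s>\n",
              nrow(x$coords), x$gamma, x$cutoff,
              if (x$n_components > 1L)
                paste0(", DISCONNECTED (", x$n_components, " parts)") else ""))
  invisible(x)
}

#' Diagonalise an ANM model
#'
#' Full symmetric eigendecomposition, eigenvalues ascending.  Modes
#' with `lambda < tol * lambda_max` are the trivial rigid-body modes;
#' for a connected non-collinear network there are exactly six, so the
#' returned nontrivial modes are numbered from `n_trivial + 1` (i.e. 7)
#' over the full spectrum.
#'
#' @param model `anm_model`.
#' @param n_modes number of nontrivial modes to return (default 6).
#' @param tol relative zero threshold (default 1e-8).
#' @return list with `eigenvalues` (full ascending spectrum),
#'   `n_trivial`, and `modes`, a list of `anm_mode` objects each
#'   holding `index` (position in the full spectrum), `eigenvalue`,
#'   `vectors` (N x 3, unit 3N-norm), `square_fluctuations`
#'   (per-node `||u_k(i)||^2 / lambda_k`), `phase_sign` (NA until
#'   [phase_orient()] is applied).
#' @export
diagonalize <- function(model, n_modes = 6L, tol = 1e-8) {
  stopifnot(inherits(model, "anm_model"))
  e <- eigen(model$hessian, symmetric = TRUE)
  lam <- rev(e$values)
  vec <- e$vectors[, rev(seq_along(e$values)), drop = FALSE]
  lam_max <- max(lam)
  if (lam_max <= 0) stop("Hessian has no positive eigenvalue")
  n_trivial <- sum(lam < tol * lam_max)
  # sanity: rigid translations must be annihilated
  n <- nrow(model$coords)
  for (k in 1:3) {
    t_k <- rep(0, 3L * n); t_k[seq(k, 3L * n, by = 3L)] <- 1 / sqrt(n)
    if (max(abs(model$hessian %*% t_k)) > 1e-8 * max(1, lam_max))
      stop("Hessian does not annihilate rigid translations; assembly error")
  }
  idx <- seq(n_trivial + 1L, length.out = min(n_modes, 3L * n - n_trivial))
  modes <- lapply(idx, function(k) {
    v <- matrix(vec[, k], ncol = 3L, byrow = TRUE)
    structure(list(index = k, eigenvalue = lam[k], vectors = v,
                   square_fluctuations = rowSums(v^2) / lam[k],
                   phase_sign = NA_real_),
              class = "anm_mode")
  })
  list(eigenvalues = lam, n_trivial = n_trivial, modes = modes)
}

#' @export
print.anm_mode <- function(x, ...) {
  cat(sprintf("<anm_mode %d: eigenvalue %.6g%s>\n", x$index, x$eigenvalue,
              if (!is.na(x$phase_sign))
                paste0(", compaction-oriented (sign ", x$phase_sign, ")")
              else ""))
  invisible(x)
}

#' Overlap between a mode and a displacement field
#'
#' Cosine of the angle between the flattened, unit-normalised mode and
#' displacement vectors.  A value of +/-1 means the observed
#' deformation is exactly the mode shape.
#'
#' @param mode `anm_mode` (or an N x 3 matrix).
#' @param displacements N x 3 matrix of per-node displacement vectors.
#' @return list with `signed` and `absolute` overlap.
#' @export
mode_overlap <- function(mode, displacements) {
  v <- if (inherits(mode, "anm_mode")) mode$vectors else as.matrix(mode)
  d <- as.matrix(displacements)
  if (!all(dim(v) == dim(d)))
    stop("mode and displacement field have different node counts")
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("zero displacement field: overlap undefined")
  ov <- sum(v * d) / (sqrt(sum(v^2)) * nd)
  list(signed = ov, absolute = abs(ov))
}

#' Orient a mode into its compaction phase
#'
#' The sign of an eigenvector is arbitrary; this fixes it so that
#' displacing the coordinates by a small positive amplitude along the
#' mode decreases the radius of gyration (the "compaction" phase).
#' When the radius-of-gyration derivative along the mode is ~0 (a pure
#' twist), the sign is set by convention (first nonzero component
#' positive) and flagged via `phase_sign = 0` stored alongside.
#'
#' @param mode `anm_mode`.
#' @param x N x 3 coordinate matrix the mode belongs to (or
#'   `anm_model`).
#' @return The mode with `vectors` possibly negated and `phase_sign`
#'   set (+1 or -1; 0 derivative flagged with attribute
#'   `rg_degenerate`).
#' @export
phase_orient <- function(mode, x) {
  stopifnot(inherits(mode, "anm_mode"))
  if (inherits(x, "anm_model")) x <- x$coords
  x <- as.matrix(x)
  v <- mode$vectors
  xc <- sweep(x, 2L, colMeans(x))
  vc <- sweep(v, 2L, colMeans(v))
  # d(Rg^2)/d(eps) at eps = 0, up to the constant 2/N
  deriv <- sum(xc * vc)
  scale_ref <- sqrt(sum(xc^2)) * sqrt(sum(vc^2))
  if (abs(deriv) < 1e-10 * max(scale_ref, 1e-300)) {
    flat <- as.numeric(t(v))
    lead <- flat[which(flat != 0)[1L]]
    sign_use <- if (is.na(lead) || lead > 0) 1 else -1
    mode$vectors <- v * sign_use
    mode$phase_sign <- sign_use
    attr(mode, "rg_degenerate") <- TRUE
    return(mode)
  }
  sign_use <- if (deriv < 0) 1 else -1
  mode$vectors <- v * sign_use
  mode$square_fluctuations <- rowSums(mode$vectors^2) / mode$eigenvalue
  mode$phase_sign <- sign_use
  mode
}
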