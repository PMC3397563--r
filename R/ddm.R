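# Difference distance analysis.
#
# The difference distance matrix (DDM) compares two conformations
# without any superposition: entry (i, j) is the change in the
# C-alpha(i)-C-alpha(j) distance from conformation A to conformation B.
# Negative entries mark residue pairs that move closer together, so a
# block of negative entries between the residues of two lobes is the
# superposition-free signature of the lobes closing on one another.

#' Pairwise distance matrix over a selection
#'
#' @param s `pdb_structure`.
#' @param sel `atom_selection` resolving to at least 2 atoms
#'   (default: all C-alpha atoms, highest-occupancy conformer).
#' @return symmetric matrix of Euclidean distances (Angstroms) with
#'   `chain:resno` dimnames.
#' @export
distance_matrix <- function(s, sel = atom_selection(atom_names = "CA")) {
  a <- resolve_selection(s, sel)
  if (nrow(a) < 2L) stop("selection must resolve to at least 2 atoms")
  m <- as.matrix(stats::dist(coords(a)))
  lab <- paste0(a$chain, ":", a$resno, a$inscode)
  dimnames(m) <- list(lab, lab)
  m
}

#' Difference distance matrix of two conformations
#'
#' Computes `d_B(i,j) - d_A(i,j)` over atoms paired by (chain, residue
#' number, insertion code, atom name).  Residues present in only one
#' structure are dropped from the comparison and recorded.
#'
#' @param a,b `pdb_structure` objects (A is the reference state; the
#'   matrix is B minus A).
#' @param sel `atom_selection` (default: all C-alpha atoms).
#' @return An object of class `ddm`: list with `values` (square matrix,
#'   Angstroms), `labels` (data.frame chain/resno/inscode), `dropped`
#'   (atom identities present in only one input).
#' @export
difference_distance <- function(a, b,
                                sel = atom_selection(atom_names = "CA")) {
  pr <- pair_atoms(a, b, sel, a_id = a$id, b_id = b$id, strict = FALSE)
  if (nrow(pr$a) < 2L) stop("fewer than 2 pairable atoms")
  da <- as.matrix(stats::dist(coords(pr$a)))
  db <- as.matrix(stats::dist(coords(pr$b)))
  v <- db - da
  lab <- paste0(pr$a$chain, ":", pr$a$resno, pr$a$inscode)
  dimnames(v) <- list(lab, lab)
  structure(list(values = v,
                 labels = data.frame(chain = pr$a$chain, resno = pr$a$resno,
                                     inscode = pr$a$inscode),
                 dropped = gsub("\r", ":", pr$dropped)),
            class = "ddm")
}

#' @export
print.ddm <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("<ddm: %d residues, mean off-diagonal %+.4f A, %.1f%% negative>\n",
              nrow(x$values), s$mean, 100 * s$fraction_negative))
  invisible(x)
}

#' Summary statistics of a difference distance matrix
#'
#' @param object `ddm`.
#' @param blocks optional named list of residue-number vectors (e.g.
#'   `list(V1 = c(55:58, 86:91, 96:101), V2 = ...)`); when given, mean
#'   entries are reported within and between blocks.
#' @param ... unused.
#' @return list with `mean`, `fraction_negative` (both over the
#'   off-diagonal), and, when `blocks` is given, `block_means` (matrix
#'   of mean entries for each block pair).
#' @export
summary.ddm <- function(object, blocks = NULL, ...) {
  v <- object$values
  off <- v[upper.tri(v)]
  out <- list(mean = mean(off), fraction_negative = mean(off < 0))
  if (!is.null(blocks)) {
    idx <- lapply(blocks, function(rr) which(object$labels$resno %in% rr))
    bm <- matrix(NA_real_, length(blocks), length(blocks),
                 dimnames = list(names(blocks), names(blocks)))
    for (i in seq_along(blocks)) for (j in seq_along(blocks)) {
      sub <- v[idx[[i]], idx[[j]], drop = FALSE]
      if (i == j) sub <- sub[upper.tri(sub)]
      bm[i, j] <- if (length(sub)) mean(sub) else NA_real_
    }
    out$block_means <- bm
  }
  out
}

#' Write a difference distance matrix as TSV
#'
#' Header comment lines record the inputs and any dropped residues;
#' the body is a labelled square matrix.
#'
#' @param x `ddm`.
#' @param path output path.
#' @param digits decimals for the entries (default 4).
#' @return `path`, invisibly.
#' @export
write_ddm <- function(x, path, digits = 4L) {
  stopifnot(inherits(x, "ddm"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(x$dropped))
    writeLines(paste0("# dropped (present in one input only): ",
                      paste(x$dropped, collapse = ", ")), con)
  lab <- rownames(x$values)
  writeLines(paste(c("residue", lab), collapse = "\t"), con)
  body <- apply(round(x$values, digits), 1L, paste, collapse = "\t")
  writeLines(paste(lab, body, sep = "\t"), con)
  invisible(path)
}
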