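# Fixtures and independent oracles used across the suite.
# Everything is built in code; no binary data.

# --- hand-written PDB text (columns transcribed from the v3.3 spec) ---
# Three-residue chain with an N-terminal pyroglutamate (hetero but
# backbone-bearing), an altloc pair on Ser3 CA, one riding hydrogen,
# an ANISOU on Ala2 CA, a sulfate and a water.
pdb_fixture_lines <- function() c(
  "CRYST1   32.230   38.160   68.920  90.00  90.00  90.00 P 21 21 21    4",
  "HETATM    1  N   PCA A   1       0.000   0.000   0.000  1.00 10.00           N",
  "HETATM    2  CA  PCA A   1       1.458   0.000   0.000  1.00 10.00           C",
  "HETATM    3  C   PCA A   1       2.009   1.420   0.000  1.00 10.00           C",
  "ATOM      4  N   ALA A   2       3.200   1.600  -0.500  1.00 10.00           N",
  "ATOM      5  CA  ALA A   2       1.000   2.000   3.000  1.00 11.00           C",
  "ANISOU    5  CA  ALA A   2    10000  10000  10000      0      0      0       C",
  "ATOM      6  C   ALA A   2       1.551   3.420   3.000  1.00 10.00           C",
  "ATOM      7  HA  ALA A   2       0.700   1.700   2.100  1.00 10.00           H",
  "ATOM      8  N   SER A   3       2.700   3.650   2.450  1.00 10.00           N",
  "ATOM      9  CA ASER A   3       3.350   4.950   2.400  0.60 12.50           C",
  "ATOM     10  CA BSER A   3       3.400   5.000   2.500  0.40 13.50           C",
  "ATOM     11  C   SER A   3       4.600   4.900   1.520  1.00 10.00           C",
  "HETATM   12  S   SO4 A 101       8.000   8.000   8.000  1.00 15.00           S",
  "HETATM   13  O1  SO4 A 101       9.200   8.000   8.000  1.00 15.00           O",
  "HETATM   14  O   HOH A 201      12.000  12.000  12.000  1.00 20.00           O",
  "END")

write_pdb_fixture <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(pdb_fixture_lines(), path)
  path
}

# --- structure builder for in-code geometry fixtures ---
# Minimal front end to pdb_structure(): supply coordinates and any
# subset of the atom columns; the rest get defaults.
make_structure <- function(xyz, name = "CA", resname = "ALA", chain = "A",
                           resno = NULL, element = "C", occ = 1, b = 10,
                           altloc = "", hetero = FALSE, id = "test") {
  xyz <- matrix(xyz, ncol = 3L)
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  atoms <- data.frame(
    serial = seq_len(n), name = rep_len(name, n),
    altloc = rep_len(altloc, n), resname = rep_len(resname, n),
    chain = rep_len(chain, n), resno = rep_len(resno, n), inscode = "",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    occ = rep_len(occ, n), b = rep_len(b, n),
    u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
    u12 = NA_real_, u13 = NA_real_, u23 = NA_real_,
    element = rep_len(element, n), hetero = rep_len(hetero, n),
    stringsAsFactors = FALSE)
  pdb_structure(atoms, id = id)
}

# --- independent rotation helpers (oracle-side, not package code) ---
rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3L, byrow = TRUE)
}
rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3L, byrow = TRUE)
}
random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_d <- qr(matrix(stats::rnorm(9L), 3L))
  R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# --- brute-force oracles ---
# Minimum RMSD over a 10-degree Euler grid of proper rotations
# (optimal translation = centroid match).  For small point sets only.
grid_rmsd_oracle <- function(P, Q, step = 10) {
  Pc <- sweep(P, 2L, colMeans(P))
  Qc <- sweep(Q, 2L, colMeans(Q))
  best <- Inf
  for (a in seq(0, 360 - step, by = step))
    for (b in seq(0, 180, by = step))
      for (g in seq(0, 360 - step, by = step)) {
        R <- rot_z(a) %*% rot_y(b) %*% rot_z(g)
        r <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
        if (r < best) best <- r
      }
  best
}

# Dense ANM Hessian assembled by an explicit double loop.
hessian_loop_oracle <- function(X, gamma = 1, cutoff = 15) {
  n <- nrow(X)
  H <- matrix(0, 3L * n, 3L * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    rij <- X[j, ] - X[i, ]
    r2 <- sum(rij^2)
    if (sqrt(r2) > cutoff) next
    blk <- -(gamma / r2) * (rij %o% rij)
    H[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <- blk
    H[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] <-
      H[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] - blk
  }
  H
}

# Orthonormal basis of the rigid-body space (3 translations + 3
# rotations about the centroid) of a coordinate set.
rigid_space <- function(X) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  B <- matrix(0, 3L * n, 6L)
  for (k in 1:3) B[seq(k, 3L * n, by = 3L), k] <- 1
  ax <- diag(3L)
  for (k in 1:3) {
    W <- t(vapply(seq_len(n), function(i) {
      v <- ax[k, ]
      c(v[2] * Xc[i, 3] - v[3] * Xc[i, 2],
        v[3] * Xc[i, 1] - v[1] * Xc[i, 3],
        v[1] * Xc[i, 2] - v[2] * Xc[i, 1])
    }, numeric(3L)))
    B[, 3L + k] <- as.numeric(t(W))
  }
  qr.Q(qr(B))
}

# Path to an optional real deposited entry; the acceptance tests fail
# (not skip) with an explanation when it is absent.
fixture_entry_path <- function(id) {
  system.file("extdata", "pdb", paste0(id, ".pdb"), package = "lobedyn")
}
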