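test_that("superposition recovers exact transforms and is optimal", {
  set.seed(42)
  P <- matrix(rnorm(30, sd = 5), ncol = 3L)
  ref <- make_structure(P)

  # self-superposition: identity, rmsd 0
  sp0 <- superpose(ref, ref, atom_selection(atom_names = "CA"))
  expect_equal(sp0$fit_rmsd, 0, tolerance = 1e-10)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-10)
  expect_true(max(abs(crossprod(sp0$rotation) - diag(3))) < 1e-10)

  # known-rotation recovery: mobile = R0 %*% x + t
  R0 <- rot_z(25) %*% rot_y(70) %*% rot_z(-40)
  t0 <- c(3, -2, 7)
  mob <- make_structure(t(R0 %*% t(P)) + rep(t0, each = nrow(P)))
  sp <- superpose(mob, ref, atom_selection(atom_names = "CA"))
  expect_equal(sp$fit_rmsd, 0, tolerance = 1e-8)
  expect_equal(sp$rotation, t(R0), tolerance = 1e-8)
  expect_true(abs(det(sp$rotation) - 1) < 1e-10)

  # optimality: never worse than the 10-degree brute-force grid
  for (case in 1:4) {
    set.seed(case)
    n <- sample(4:10, 1L)
    A <- matrix(rnorm(3 * n, sd = 4), ncol = 3L)
    B <- matrix(rnorm(3 * n, sd = 4), ncol = 3L)
    got <- superpose(make_structure(A), make_structure(B),
                     atom_selection(atom_names = "CA"))$fit_rmsd
    expect_lte(got, grid_rmsd_oracle(A, B) + 1e-9)
  }
})

test_that("superposition RMSD is symmetric in its arguments", {
  set.seed(7)
  A <- make_structure(matrix(rnorm(24, sd = 3), ncol = 3L))
  B <- make_structure(matrix(rnorm(24, sd = 3), ncol = 3L))
  sel <- atom_selection(atom_names = "CA")
  expect_equal(superpose(A, B, sel)$fit_rmsd,
               superpose(B, A, sel)$fit_rmsd, tolerance = 1e-8)
})

test_that("superposition rejects degenerate and unpairable inputs", {
  line <- make_structure(cbind(1:5, 0, 0))
  expect_error(superpose(line, line, atom_selection(atom_names = "CA")),
               "collinear")
  two <- make_structure(matrix(rnorm(6), ncol = 3L))
  expect_error(superpose(two, two, atom_selection(atom_names = "CA")),
               "at least 3")
  a <- make_structure(matrix(rnorm(30), ncol = 3L))
  b <- make_structure(matrix(rnorm(27), ncol = 3L))   # residue 10 missing
  expect_error(superpose(a, b, atom_selection(atom_names = "CA")),
               "missing in")
  # strict = FALSE uses the pairable intersection instead
  expect_equal(superpose(a, b, atom_selection(atom_names = "CA"),
                         strict = FALSE)$n_fit, 9L)
})

test_that("displacement vectors are reference minus transformed mobile", {
  set.seed(11)
  X <- matrix(rnorm(30, sd = 5), ncol = 3L)
  ref <- make_structure(X)
  shift <- c(0.3, -0.4, 0.2)
  Y <- X
  Y[10L, ] <- Y[10L, ] + shift     # move one atom, fit on the others
  mob <- make_structure(Y)
  fit_sel <- atom_selection(ranges = c("A", 1, 9), atom_names = "CA")
  all_sel <- atom_selection(atom_names = "CA")
  sp <- superpose(mob, ref, fit_sel, report_sel = all_sel)
  expect_equal(sp$fit_rmsd, 0, tolerance = 1e-8)
  d10 <- as.numeric(sp$displacements[10L, c("dx", "dy", "dz")])
  expect_equal(d10, -shift, tolerance = 1e-8)
  expect_equal(sp$displacements$norm[10L], sqrt(sum(shift^2)),
               tolerance = 1e-8)
})

test_that("radius of gyration has its closed forms and invariances", {
  one <- make_structure(c(4, 5, 6))
  expect_equal(radius_of_gyration(one), 0)
  # two equal masses separated by d -> d/2
  two <- make_structure(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(radius_of_gyration(two), 1.5, tolerance = 1e-12)
  # unequal masses: C (12.011) and O (15.999) at distance 2
  co <- make_structure(rbind(c(0, 0, 0), c(2, 0, 0)), element = c("C", "O"))
  mC <- 12.011; mO <- 15.999
  com <- 2 * mO / (mC + mO)
  expect_equal(radius_of_gyration(co),
               sqrt((mC * com^2 + mO * (2 - com)^2) / (mC + mO)),
               tolerance = 1e-12)
  # rigid-motion invariance and linear scaling
  set.seed(3)
  X <- matrix(rnorm(60, sd = 6), ncol = 3L)
  s <- make_structure(X, element = sample(c("C", "N", "O", "S"), 20, TRUE))
  rg <- radius_of_gyration(s)
  R <- random_rotation()
  moved <- make_structure(t(R %*% t(X)) + 5, element = s$atoms$element)
  expect_equal(radius_of_gyration(moved), rg, tolerance = 1e-9)
  scaled <- make_structure(2.5 * X, element = s$atoms$element)
  expect_equal(radius_of_gyration(scaled), 2.5 * rg, tolerance = 1e-9)
  # errors
  expect_error(radius_of_gyration(
    make_structure(c(0, 0, 0), element = "XX")), "atomic mass")
})

test_that("atom distances and group minima resolve specs deterministically", {
  s <- read_pdb(write_pdb_fixture())
  expect_equal(atom_distance(s, "A:2:CA", "A:2:CA"), 0)
  # constructed 3-4-5 triangle
  tri <- make_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)))
  expect_equal(atom_distance(tri, "A:1:CA", "A:3:CA"), 5, tolerance = 1e-12)
  expect_error(atom_distance(s, "A:2:CA", "A:99:XX"), "A:99:XX")

  # min distance: constructed distances 2, 1, 3 -> picks the middle atom
  grp <- make_structure(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 0, 0), c(3, 0, 0)))
  res <- min_distance_to_group(
    grp, "A:1:CA", atom_selection(ranges = c("A", 2, 4), atom_names = "CA"))
  expect_equal(res$distance, 1)
  expect_equal(res$atom$resno, 3L)
  # duplicate of the query position -> zero
  dup <- make_structure(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 0, 0)))
  expect_equal(min_distance_to_group(
    dup, "A:1:CA", atom_selection(ranges = c("A", 2, 3),
                                  atom_names = "CA"))$distance, 0)
  # tie broken by serial
  tie <- make_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0)))
  expect_equal(min_distance_to_group(
    tie, "A:1:CA", atom_selection(ranges = c("A", 2, 3),
                                  atom_names = "CA"))$atom$serial, 2L)
})

# build a 2-residue backbone whose omega torsion is exactly `target`
omega_backbone <- function(target_deg) {
  ca0 <- c(1, 0, 0); c0 <- c(0, 0, 0); n1 <- c(0, 1, 0)
  # rotate the CA0 half-plane direction about the C-N bond axis
  u <- ca0 - c0
  axis <- (n1 - c0) / sqrt(sum((n1 - c0)^2))
  th <- target_deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3L, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  ca1 <- n1 + as.numeric(R %*% u)
  rbind(CA0 = ca0, C0 = c0, N1 = n1, CA1 = ca1)
}

test_that("omega dihedrals follow the residue-i convention in [0, 360)", {
  build <- function(pts) {
    atoms <- rbind(
      data.frame(serial = 1:2, name = c("CA", "C"), resno = 1L,
                 x = pts[1:2, 1], y = pts[1:2, 2], z = pts[1:2, 3]),
      data.frame(serial = 3:4, name = c("N", "CA"), resno = 2L,
                 x = pts[3:4, 1], y = pts[3:4, 2], z = pts[3:4, 3]))
    s <- make_structure(as.matrix(atoms[, c("x", "y", "z")]),
                        name = atoms$name, resno = atoms$resno)
    s
  }
  # ideal trans peptide -> 180; constructed 90 -> 90; -167.9 -> 192.1
  for (target in c(180, 90, 192.1, 270, 12.5)) {
    om <- omega_dihedrals(build(omega_backbone(target)))
    expect_equal(nrow(om), 1L)
    expect_equal(om$resno, 2L)             # bond assigned to residue i
    expect_equal(om$omega, target %% 360, tolerance = 1e-8)
  }
  # chain break: C...N further than 2.5 A -> bond skipped
  pts <- omega_backbone(180)
  pts["N1", ] <- pts["N1", ] + c(0, 5, 0)
  pts["CA1", ] <- pts["CA1", ] + c(0, 5, 0)
  expect_equal(nrow(omega_dihedrals(build(pts))), 0L)
})

test_that("dihedrals are rigid-motion invariant and mirror-negated", {
  set.seed(9)
  for (target in c(70, 192.1)) {
    pts <- omega_backbone(target)
    R <- random_rotation()
    moved <- t(R %*% t(pts)) + rep(c(2, -1, 4), each = 4L)
    mirrored <- pts %*% diag(c(1, 1, -1))
    di <- function(p) lobedyn:::dihedral4(p[1, ], p[2, ], p[3, ], p[4, ]) %% 360
    expect_equal(di(moved), target %% 360, tolerance = 1e-8)
    expect_equal(di(mirrored), (360 - target) %% 360, tolerance = 1e-8)
  }
})
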