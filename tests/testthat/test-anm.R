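test_that("the dimer has its closed-form spectrum", {
  for (gamma in c(1, 2.5)) {
    m <- build_hessian(rbind(c(0, 0, 0), c(3, 0, 0)), gamma = gamma)
    dec <- diagonalize(m, n_modes = 1L)
    # collinear pair: 5 zero modes, one stretch mode at exactly 2*gamma
    expect_equal(dec$n_trivial, 5L)
    expect_equal(dec$modes[[1L]]$eigenvalue, 2 * gamma, tolerance = 1e-12)
    expect_equal(dec$modes[[1L]]$index, 6L)
    # eigenvector along the bond
    v <- dec$modes[[1L]]$vectors
    expect_equal(abs(v[, 1L]), rep(1 / sqrt(2), 2L), tolerance = 1e-10)
    expect_equal(max(abs(v[, 2:3])), 0, tolerance = 1e-10)
  }
})

test_that("hessian assembly matches an independent double-loop oracle", {
  # unit tetrahedron
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  m <- build_hessian(tet, gamma = 1.7, cutoff = 15)
  expect_equal(m$hessian, hessian_loop_oracle(tet, gamma = 1.7), tolerance = 1e-12)
  expect_equal(sort(eigen(m$hessian, symmetric = TRUE)$values),
               sort(eigen(hessian_loop_oracle(tet, gamma = 1.7),
                          symmetric = TRUE)$values), tolerance = 1e-10)

  # random connected cloud with a finite cutoff actually excluding pairs
  set.seed(12)
  X <- matrix(rnorm(36, sd = 4), ncol = 3L)
  m2 <- build_hessian(X, cutoff = 8)
  expect_equal(m2$hessian, hessian_loop_oracle(X, cutoff = 8),
               tolerance = 1e-12)
  expect_equal(m2$hessian, t(m2$hessian))
})

test_that("hessian obeys the rigid-body null space and spectral invariances", {
  s <- make_two_lobe(seed = 1L)
  X <- coords(s)
  m <- build_hessian(X)
  n <- nrow(X)

  # translational block-sum: H annihilates the 3 unit translations
  for (k in 1:3) {
    t_k <- rep(0, 3L * n); t_k[seq(k, 3L * n, by = 3L)] <- 1
    expect_lt(max(abs(m$hessian %*% t_k)), 1e-6)
  }
  # full rigid-body space (translations + rotations about the centroid)
  B <- rigid_space(X)
  expect_lt(max(abs(m$hessian %*% B)), 1e-6 * norm(m$hessian, "2"))

  dec <- diagonalize(m)
  expect_equal(dec$n_trivial, 6L)
  expect_gt(dec$eigenvalues[7L], 1e-6)

  # spectrum invariant under rigid rotation of the input
  R <- rot_z(33) %*% rot_y(-57)
  m_rot <- build_hessian(t(R %*% t(X)) + rep(c(5, 6, 7), each = n))
  expect_equal(diagonalize(m_rot)$eigenvalues, dec$eigenvalues,
               tolerance = 1e-10)

  # gamma is a pure scale: eigenvalues proportional, modes unchanged
  m_g <- build_hessian(X, gamma = 3.2)
  dec_g <- diagonalize(m_g)
  expect_equal(dec_g$eigenvalues, 3.2 * dec$eigenvalues, tolerance = 1e-8)
  for (k in seq_along(dec$modes))
    expect_equal(abs(mode_overlap(dec$modes[[k]],
                                  dec_g$modes[[k]]$vectors)$signed), 1,
                 tolerance = 1e-6)

  # mode vectors are unit and orthogonal
  V <- vapply(dec$modes, function(mm) as.numeric(t(mm$vectors)),
              numeric(3L * n))
  expect_equal(crossprod(V), diag(length(dec$modes)), tolerance = 1e-8)
  expect_equal(vapply(dec$modes, function(mm)
    sum(mm$vectors^2), numeric(1L)), rep(1, length(dec$modes)),
    tolerance = 1e-10)
  expect_true(all(vapply(dec$modes, function(mm)
    all(mm$square_fluctuations >= 0), logical(1L))))
})

test_that("degenerate networks are rejected or flagged", {
  expect_error(build_hessian(rbind(c(0, 0, 0), c(0, 0, 0), c(5, 0, 0))),
               "duplicate")
  # two far-apart dimers: disconnected -> warning, > 6 trivial modes
  far <- rbind(c(0, 0, 0), c(3, 0, 0), c(100, 0, 0), c(103, 0, 0))
  expect_warning(m <- build_hessian(far), "disconnected")
  expect_gt(diagonalize(m, n_modes = 1L)$n_trivial, 6L)
  expect_error(build_hessian(matrix(1, 1L, 3L)), "at least 2")
})

test_that("mode overlap is a cosine with the eigenbasis properties", {
  s <- make_two_lobe(seed = 5L, n_lobe_a = 6L, n_lobe_b = 6L)
  m <- build_hessian(coords(s))
  dec <- diagonalize(m, n_modes = 10L)
  m7 <- dec$modes[[1L]]

  expect_equal(mode_overlap(m7, m7$vectors)$signed, 1, tolerance = 1e-12)
  expect_equal(mode_overlap(m7, 5 * m7$vectors)$signed, 1, tolerance = 1e-12)
  expect_equal(mode_overlap(m7, dec$modes[[2L]]$vectors)$signed, 0,
               tolerance = 1e-10)
  expect_error(mode_overlap(m7, 0 * m7$vectors), "zero displacement")
  expect_error(mode_overlap(m7, m7$vectors[-1L, ]), "node counts")

  # completeness: a random field with the rigid-body part projected out
  # decomposes over the nontrivial modes with sum of squared overlaps 1
  n <- nrow(m$coords)
  dec_all <- diagonalize(m, n_modes = 3L * n)
  set.seed(14)
  d <- rnorm(3L * n)
  B <- rigid_space(m$coords)
  d <- d - B %*% crossprod(B, d)
  D <- matrix(d, ncol = 3L, byrow = TRUE)
  ov2 <- vapply(dec_all$modes, function(mm)
    mode_overlap(mm, D)$signed^2, numeric(1L))
  expect_equal(sum(ov2), 1, tolerance = 1e-10)
})

test_that("phase orientation picks the compacting sign and is idempotent", {
  s <- make_two_lobe(seed = 3L)
  m <- build_hessian(coords(s))
  mode7 <- diagonalize(m, n_modes = 1L)$modes[[1L]]
  rg <- function(Y) {
    cc <- colMeans(Y); sqrt(mean(rowSums(sweep(Y, 2L, cc)^2)))
  }
  po <- phase_orient(mode7, m)
  expect_true(po$phase_sign %in% c(-1, 1))
  eps <- 0.4
  expect_lt(rg(m$coords + eps * po$vectors), rg(m$coords))

  # idempotent; and invariant to the solver's arbitrary input sign
  po2 <- phase_orient(po, m)
  expect_equal(po2$vectors, po$vectors, tolerance = 1e-12)
  flipped <- mode7
  flipped$vectors <- -flipped$vectors
  expect_equal(phase_orient(flipped, m)$vectors, po$vectors,
               tolerance = 1e-12)

  # pure-twist degenerate case: flagged, deterministic convention
  twist <- mode7
  # construct a divergence-free field: rotate about z through centroid
  Xc <- sweep(m$coords, 2L, colMeans(m$coords))
  W <- cbind(-Xc[, 2L], Xc[, 1L], 0)
  twist$vectors <- W / sqrt(sum(W^2))
  tw <- phase_orient(twist, m)
  expect_true(isTRUE(attr(tw, "rg_degenerate")))
  expect_equal(phase_orient(tw, m)$vectors, tw$vectors, tolerance = 1e-12)
})

test_that("the toy's softest mode is the hinge pincer", {
  s <- make_two_lobe(seed = 1L)
  m <- build_hessian(coords(s))
  dec <- diagonalize(m, n_modes = 3L)
  cl <- close_hinge(s, 5)
  sp <- superpose(cl, s, atom_selection(atom_names = "CA"))
  D <- as.matrix(sp$displacements[, c("dx", "dy", "dz")])
  expect_gt(mode_overlap(dec$modes[[1L]], D)$absolute, 0.9)
  # and the closing phase compacts: the oriented mode agrees in sign
  # with the closed-minus-open field (D is reference minus transformed
  # mobile, i.e. open minus closed, hence the negation)
  po <- phase_orient(dec$modes[[1L]], m)
  expect_gt(mode_overlap(po, -D)$signed, 0.9)
})
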