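# Synthetic structure generators.
#
# The two-lobe toy emulates the topology the analyses assume: two
# compact clusters ("lobes") joined through a thin neck at a hinge, so
# that the softest deformations are relative motions of the lobes.
# Geometry (all in the laboratory frame):
#   * the hinge sits at the origin; the two arms radiate in the xy
#     plane at +/- `half_angle` from the +y axis;
#   * each arm carries pairs of neck nodes at z = +/- neck_z -- the
#     vertical spread stiffens out-of-plane bending and torsion so that
#     the soft in-plane pincer (closing) motion dominates;
#   * each lobe is a uniform ball of nodes at the arm tip, far enough
#     apart that the lobes interact only through the neck at the
#     default 15 Angstrom cutoff.
# Closing the hinge rotates the whole B side about the z axis through
# the hinge.  Because that rotation preserves every node's cylindrical
# radius and height and strictly reduces every cross-lobe azimuthal
# separation, ALL inter-lobe distances shrink -- the difference
# distance matrix of the pair is negative on the whole inter-lobe
# block by construction.

#' Generate a two-lobe toy structure
#'
#' @param n_lobe_a,n_lobe_b nodes per lobe (>= 4 each; default 20).
#' @param arm_length hinge-to-lobe-centre distance, Angstroms
#'   (default 16).
#' @param half_angle half the opening angle of the V, degrees from the
#'   +y axis (default 50; lobe centres are then
#'   `2 * arm_length * sin(half_angle)` apart).
#' @param lobe_radius radius of each lobe's node ball, Angstroms
#'   (default 3.5).
#' @param neck_positions distances of neck node pairs along each arm,
#'   Angstroms (default `c(4, 8)`).
#' @param neck_z half the vertical spread of the neck plates,
#'   Angstroms (default 2).
#' @param seed integer seed; the generator is fully deterministic for
#'   a fixed seed.
#' @param cutoff connectivity is verified at this cutoff (default 15);
#'   a disconnected result is an error.
#' @return A `pdb_structure` of CA-only ALA residues (chain A,
#'   sequential numbering, occupancy 1), with attributes `lobe`
#'   (per-atom labels: `"H"` hinge, `"nA"`/`"nB"` neck, `"A"`/`"B"`
#'   lobe) and `hinge` (list with `point` and `axis`).
#' @export
make_two_lobe <- function(n_lobe_a = 20L, n_lobe_b = 20L, arm_length = 16,
                          half_angle = 50, lobe_radius = 3.5,
                          neck_positions = c(4, 8), neck_z = 2,
                          seed = 1L, cutoff = 15) {
  stopifnot(n_lobe_a >= 4L, n_lobe_b >= 4L)
  dir_a <- c(-sin(half_angle * pi / 180), cos(half_angle * pi / 180), 0)
  dir_b <- c(sin(half_angle * pi / 180), cos(half_angle * pi / 180), 0)

  ball <- function(n, centre, radius) {
    # uniform ball: isotropic directions, radii ~ R * U^(1/3)
    v <- matrix(stats::rnorm(3L * n), ncol = 3L)
    v <- v / sqrt(rowSums(v^2))
    r <- radius * stats::runif(n)^(1 / 3)
    sweep(v * r, 2L, centre, `+`)
  }
  neck <- function(dir) {
    do.call(rbind, lapply(neck_positions, function(t)
      rbind(t * dir + c(0, 0, neck_z), t * dir - c(0, 0, neck_z))))
  }

  pts <- with_seed(seed, {
    hinge <- rbind(c(0, 0, neck_z), c(0, 0, -neck_z))
    la <- ball(n_lobe_a, arm_length * dir_a, lobe_radius)
    lb <- ball(n_lobe_b, arm_length * dir_b, lobe_radius)
    list(hinge = hinge, neck_a = neck(dir_a), neck_b = neck(dir_b),
         lobe_a = la, lobe_b = lb)
  })
  xyz <- rbind(pts$hinge, pts$neck_a, pts$lobe_a, pts$neck_b, pts$lobe_b)
  lobe <- c(rep("H", nrow(pts$hinge)), rep("nA", nrow(pts$neck_a)),
            rep("A", n_lobe_a), rep("nB", nrow(pts$neck_b)),
            rep("B", n_lobe_b))
  n <- nrow(xyz)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", altloc = "", resname = "ALA",
    chain = "A", resno = seq_len(n), inscode = "",
    x = round(xyz[, 1L], 3L), y = round(xyz[, 2L], 3L),
    z = round(xyz[, 3L], 3L),
    occ = 1, b = 10,
    u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
    u12 = NA_real_, u13 = NA_real_, u23 = NA_real_,
    element = "C", hetero = FALSE, stringsAsFactors = FALSE)
  s <- pdb_structure(atoms, id = sprintf("two_lobe_seed%d", seed))
  d <- as.matrix(stats::dist(coords(s)))
  adj <- d <= cutoff; diag(adj) <- FALSE
  if (graph_components(adj) > 1L)
    stop("generated network is disconnected at cutoff ", cutoff,
         " Angstroms; widen the geometry parameters")
  attr(s, "lobe") <- lobe
  attr(s, "hinge") <- list(point = c(0, 0, 0), axis = c(0, 0, 1))
  s
}

#' Close the hinge of a two-lobe toy
#'
#' Rotates the whole B side (lobe B plus its neck) about the hinge
#' axis, moving it toward lobe A.  For the default geometry every
#' inter-lobe distance strictly decreases, so the difference distance
#' matrix of (original, closed) is negative on the entire inter-lobe
#' block.
#'
#' @param s a structure from [make_two_lobe()].
#' @param angle closing angle in degrees (default 5; positive closes).
#' @return The rotated `pdb_structure` (lobe attributes preserved).
#' @export
close_hinge <- function(s, angle = 5) {
  lobe <- attr(s, "lobe")
  hinge <- attr(s, "hinge")
  if (is.null(lobe) || is.null(hinge))
    stop("not a two-lobe toy structure (missing lobe/hinge attributes)")
  # +angle about +z carries the B arm (at azimuth 90 - half_angle
  # degrees) toward the A arm
  R <- rotation_about_axis(hinge$axis, angle)
  move <- lobe %in% c("B", "nB")
  X <- coords(s)
  X[move, ] <- sweep(sweep(X[move, , drop = FALSE], 2L, hinge$point) %*% t(R),
                     2L, hinge$point, `+`)
  out <- s
  out$atoms$x <- round(X[, 1L], 3L)
  out$atoms$y <- round(X[, 2L], 3L)
  out$atoms$z <- round(X[, 3L], 3L)
  out$id <- paste0(s$id, "_closed")
  out
}

#' Displace a structure along a normal mode
#'
#' Builds a conformer related to `base` by a known deformation:
#' coordinates move by `amplitude * mode$vectors` (the mode is a unit
#' 3N-vector, so the largest per-node displacement is `amplitude`
#' times the largest per-node vector norm, exactly).
#'
#' @param base `pdb_structure` whose ordered CA atoms correspond to the
#'   mode's nodes.
#' @param mode `anm_mode` (typically [phase_orient()]ed first).
#' @param amplitude displacement scale in Angstroms.
#' @param round_coords round output coordinates to PDB precision
#'   (3 decimals, default `FALSE` so exact-construction identities
#'   hold in memory).
#' @return The displaced `pdb_structure`.
#' @export
make_conformer_pair <- function(base, mode, amplitude,
                                round_coords = FALSE) {
  stopifnot(inherits(base, "pdb_structure"), inherits(mode, "anm_mode"))
  X <- coords(base)
  if (!all(dim(X) == dim(mode$vectors)))
    stop("mode node count does not match the structure")
  X <- X + amplitude * mode$vectors
  if (round_coords) X <- round(X, 3L)
  out <- base
  out$atoms$x <- X[, 1L]
  out$atoms$y <- X[, 2L]
  out$atoms$z <- X[, 3L]
  out$id <- sprintf("%s_mode%d_amp%g", base$id, mode$index, amplitude)
  out
}

#' Plant anisotropic U tensors with a known eigenvalue ratio
#'
#' Each atom receives `U = R diag(scale, g * scale, ratio * scale) R^T`
#' with the largest principal axis along `axis_field` and `g` drawn
#' uniformly in `[ratio, 1]`, so the recovered anisotropy is exactly
#' `ratio` (up to ANISOU quantisation when written to file: U entries
#' round to 1e-4 square Angstroms, perturbing A by roughly
#' `1.5e-4 * (1 + ratio) / scale`).
#'
#' @param s `pdb_structure`.
#' @param axis_field N x 3 matrix of per-atom principal-axis
#'   directions, or `NULL` for random directions.
#' @param ratio target anisotropy in (0, 1].
#' @param scale largest eigenvalue in square Angstroms (default 0.5).
#' @param seed integer seed for `g` (and the axes when random).
#' @return `s` with `u11..u23` populated.
#' @export
make_synthetic_adps <- function(s, axis_field = NULL, ratio, scale = 0.5,
                                seed = 1L) {
  stopifnot(inherits(s, "pdb_structure"), ratio > 0, ratio <= 1, scale > 0)
  n <- nrow(s$atoms)
  with_seed(seed, {
    if (is.null(axis_field)) {
      axis_field <- matrix(stats::rnorm(3L * n), ncol = 3L)
    }
    axis_field <- as.matrix(axis_field)
    stopifnot(nrow(axis_field) == n, ncol(axis_field) == 3L)
    axis_field <- axis_field / sqrt(rowSums(axis_field^2))
    g <- stats::runif(n, ratio, 1)
    for (i in seq_len(n)) {
      B <- orthonormal_basis(axis_field[i, ])
      U <- B %*% diag(c(scale, g[i] * scale, ratio * scale)) %*% t(B)
      s$atoms[i, c("u11", "u22", "u33", "u12", "u13", "u23")] <-
        c(U[1L, 1L], U[2L, 2L], U[3L, 3L], U[1L, 2L], U[1L, 3L], U[2L, 3L])
    }
  })
  s$atoms$b <- vapply(seq_len(n), function(i)
    b_eq(u_tensor(s$atoms[i, , drop = FALSE])), numeric(1L))
  s
}
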