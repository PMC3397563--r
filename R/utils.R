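# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so generators are
#' reproducible without leaking state into the caller's session.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Cross product of two 3-vectors
#' @noRd
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Rotation matrix about an arbitrary axis (Rodrigues), column-vector
#' convention: x' = R %*% x.
#' @noRd
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3L], u[2L],
                u[3L], 0, -u[1L],
                -u[2L], u[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Complete a unit vector into a right-handed orthonormal basis
#' (returned as columns; first column equals the input direction).
#' @noRd
orthonormal_basis <- function(v) {
  v <- v / sqrt(sum(v^2))
  # pick the world axis least aligned with v to seed the second vector
  seed <- diag(3L)[, which.min(abs(v))]
  e2 <- seed - sum(seed * v) * v
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- cross3(v, e2)
  cbind(v, e2, e3, deparse.level = 0L)
}

# Standard atomic weights (IUPAC 2021, rounded), keyed by element symbol
# as found in PDB columns 77-78.  Deuterium kept distinct.
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, MG = 24.305, K = 39.098, CA = 40.078, MN = 54.938,
  FE = 55.845, CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38
)

#' Atomic mass lookup by element symbol
#' @noRd
atomic_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .atomic_masses[key]
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    stop("no atomic mass tabulated for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(m)
}

#' Format a number for fixed-width PDB fields
#' @noRd
fmt_fixed <- function(x, width, digits) {
  formatC(x, format = "f", digits = digits, width = width)
}
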