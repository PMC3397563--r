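# Fixed-column PDB (v3.3) reading and writing.
#
# Only the records the analyses consume are interpreted: ATOM, HETATM,
# ANISOU, CRYST1, TER, MODEL/ENDMDL (first model only).  ANISOU values
# are stored in the file as U * 1e4; they are converted to U in square
# Angstroms at parse time.

#' Read a PDB-format coordinate file
#'
#' @param path path to a PDB file.
#' @param id identifier for the resulting structure; defaults to the
#'   file stem.
#' @return A [pdb_structure].  ANISOU records are attached to their
#'   ATOM/HETATM rows by serial number; an ANISOU with no matching
#'   serial raises a warning and is dropped.  Malformed fixed-width
#'   fields raise an error naming the offending line.
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)

  # restrict to the first MODEL when the file is multi-model
  model_at <- which(rec == "MODEL ")
  if (length(model_at)) {
    endmdl <- which(rec == "ENDMDL")
    last <- if (length(endmdl)) endmdl[1L] else length(lines)
    inside <- seq(model_at[1L], last)
    drop <- setdiff(which(rec %in% c("ATOM  ", "HETATM", "ANISOU")), inside)
    if (length(drop)) { lines <- lines[-drop]; rec <- rec[-drop] }
  }

  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_aniso <- rec == "ANISOU"
  if (!any(is_atom)) stop("no ATOM or HETATM records in ", path)

  num_field <- function(txt, from, to, what, lineno, integer = FALSE) {
    raw <- trimws(substr(txt, from, to))
    val <- suppressWarnings(if (integer) as.integer(raw) else as.numeric(raw))
    bad <- is.na(val) & raw != ""
    bad <- bad | raw == ""
    if (any(bad))
      stop("malformed ", what, " field in PDB record at line ",
           lineno[which(bad)[1L]], call. = FALSE)
    val
  }

  al <- lines[is_atom]
  ln <- which(is_atom)
  atoms <- data.frame(
    serial  = num_field(al, 7L, 11L, "serial", ln, integer = TRUE),
    name    = substr(al, 13L, 16L),
    altloc  = trimws(substr(al, 17L, 17L)),
    resname = trimws(substr(al, 18L, 20L)),
    chain   = substr(al, 22L, 22L),
    resno   = num_field(al, 23L, 26L, "residue number", ln, integer = TRUE),
    inscode = trimws(substr(al, 27L, 27L)),
    x = num_field(al, 31L, 38L, "x", ln),
    y = num_field(al, 39L, 46L, "y", ln),
    z = num_field(al, 47L, 54L, "z", ln),
    occ = num_field(al, 55L, 60L, "occupancy", ln),
    b   = num_field(al, 61L, 66L, "B-factor", ln),
    u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
    u12 = NA_real_, u13 = NA_real_, u23 = NA_real_,
    element = trimws(substr(al, 77L, 78L)),
    hetero  = rec[is_atom] == "HETATM",
    stringsAsFactors = FALSE)

  if (any(is_aniso)) {
    ul <- lines[is_aniso]
    un <- which(is_aniso)
    userial <- num_field(ul, 7L, 11L, "serial", un, integer = TRUE)
    ucols <- vapply(seq_len(6L), function(k) {
      from <- 29L + (k - 1L) * 7L
      num_field(ul, from, from + 6L, paste0("U", k), un, integer = TRUE)
    }, integer(length(userial)))
    ucols <- matrix(ucols, ncol = 6L)
    row <- match(userial, atoms$serial)
    if (anyNA(row)) {
      warning("dropping ", sum(is.na(row)),
              " ANISOU record(s) with no matching ATOM serial in ", path)
      ucols <- ucols[!is.na(row), , drop = FALSE]
      row <- row[!is.na(row)]
    }
    # file order: U11 U22 U33 U12 U13 U23, scaled by 1e4
    atoms[row, c("u11", "u22", "u33", "u12", "u13", "u23")] <- ucols / 1e4
  }

  unit_cell <- NULL
  spacegroup <- NULL
  cry <- which(rec == "CRYST1")
  if (length(cry)) {
    cl <- lines[cry[1L]]
    unit_cell <- c(a = as.numeric(substr(cl, 7L, 15L)),
                   b = as.numeric(substr(cl, 16L, 24L)),
                   c = as.numeric(substr(cl, 25L, 33L)),
                   alpha = as.numeric(substr(cl, 34L, 40L)),
                   beta  = as.numeric(substr(cl, 41L, 47L)),
                   gamma = as.numeric(substr(cl, 48L, 54L)))
    spacegroup <- trimws(substr(cl, 56L, 66L))
    if (anyNA(unit_cell))
      stop("malformed CRYST1 record at line ", cry[1L])
  }

  pdb_structure(atoms, id = id, unit_cell = unit_cell,
                spacegroup = spacegroup)
}

#' Write a structure to a PDB-format file
#'
#' Emits CRYST1 (when a unit cell is present), ATOM/HETATM and, for
#' atoms carrying U tensors, ANISOU records (U * 1e4, rounded to
#' integers per the format).
#'
#' @param s `pdb_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "pdb_structure"))
  a <- s$atoms
  out <- character(0L)
  if (!is.null(s$unit_cell)) {
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                          s$unit_cell[1L], s$unit_cell[2L], s$unit_cell[3L],
                          s$unit_cell[4L], s$unit_cell[5L], s$unit_cell[6L],
                          if (is.null(s$spacegroup)) "P 1" else s$spacegroup,
                          1L))
  }
  if (nrow(a)) {
    name4 <- vapply(a$name, function(n) {
      # names read from file keep their original 4-char field; pad
      # fresh names per convention (element-right-justified in 13-14)
      if (nchar(n) == 4L) n
      else if (nchar(trimws(n)) <= 3L) sprintf(" %-3s", trimws(n))
      else sprintf("%-4s", trimws(n))
    }, character(1L), USE.NAMES = FALSE)
    atom_lines <- sprintf(
      "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(a$hetero, "HETATM", "ATOM"),
      a$serial, name4, a$altloc, a$resname, a$chain, a$resno, a$inscode,
      a$x, a$y, a$z, a$occ, a$b, a$element)
    has_u <- !is.na(a$u11)
    if (any(has_u)) {
      ua <- a[has_u, , drop = FALSE]
      aniso_lines <- sprintf(
        "ANISOU%5d %-4s%1s%-3s %1s%4d%1s %7d%7d%7d%7d%7d%7d      %2s",
        ua$serial, name4[has_u], ua$altloc, ua$resname, ua$chain, ua$resno,
        ua$inscode,
        as.integer(round(ua$u11 * 1e4)), as.integer(round(ua$u22 * 1e4)),
        as.integer(round(ua$u33 * 1e4)), as.integer(round(ua$u12 * 1e4)),
        as.integer(round(ua$u13 * 1e4)), as.integer(round(ua$u23 * 1e4)),
        ua$element)
      merged <- character(nrow(a) + sum(has_u))
      pos <- seq_len(nrow(a)) + cumsum(has_u) - has_u
      merged[pos] <- atom_lines
      merged[pos[has_u] + 1L] <- aniso_lines
      atom_lines <- merged
    }
    out <- c(out, atom_lines)
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
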