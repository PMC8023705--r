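# Molecular geometry container and XYZ input.

#' Create a molecule
#'
#' A molecule is a set of atoms with element symbols, nuclear charges and
#' Cartesian positions in bohr. Positions are stored as an n x 3 matrix.
#'
#' @param element Character vector of element symbols.
#' @param coords n x 3 numeric matrix of positions in bohr.
#' @param charge Optional integer vector of nuclear charges; derived from
#'   the element symbols when omitted and checked for consistency otherwise.
#' @return An object of class `molecule` with fields `element`, `charge`,
#'   `coords` (bohr).
#' @export
molecule <- function(element, coords, charge = NULL) {
  coords <- as.matrix(coords)
  if (length(element) < 1L) stop("a molecule needs at least one atom")
  if (!is.numeric(coords) || ncol(coords) != 3L ||
      nrow(coords) != length(element)) {
    stop("coords must be a numeric matrix with one row of 3 per atom")
  }
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  zref <- element_charge(element)
  if (is.null(charge)) {
    charge <- zref
  } else if (!isTRUE(all(as.integer(charge) == zref))) {
    stop("nuclear charges inconsistent with element symbols")
  }
  structure(
    list(element = as.character(element), charge = as.integer(charge),
         coords = unname(coords)),
    class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms (%s)>\n", length(x$element),
              paste(x$element, collapse = " ")))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A [molecule()].
#' @return Integer count.
#' @export
n_atoms <- function(mol) length(mol$element)

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `element x y z` line per atom. Coordinates are converted to bohr.
#'
#' @param path Path to the file.
#' @param unit Unit of the coordinates in the file: `"angstrom"` (default,
#'   the XYZ convention) or `"bohr"`.
#' @return A [molecule()] with coordinates in bohr.
#' @export
read_xyz <- function(path, unit = c("angstrom", "bohr")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("XYZ parse error at line 1: empty file")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) {
    stop("XYZ parse error at line 1: expected a positive atom count")
  }
  if (length(lines) < n + 2L) {
    stop(sprintf("XYZ parse error: count line says %d atoms but only %d atom lines present",
                 n, max(0L, length(lines) - 2L)))
  }
  element <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) < 4L) {
      stop(sprintf("XYZ parse error at line %d: expected 'element x y z'", ln))
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) {
      stop(sprintf("XYZ parse error at line %d: non-numeric coordinate", ln))
    }
    element[i] <- tok[1L]
    coords[i, ] <- xyz
  }
  if (unit == "angstrom") {
    coords <- coords * shieldens_constants$bohr_per_angstrom
  }
  molecule(element, coords)
}

#' Write a molecule to an XYZ file
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @param unit Unit to write: `"angstrom"` (default) or `"bohr"`.
#' @param comment Comment line content.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, unit = c("angstrom", "bohr"),
                      comment = "written by shieldens") {
  unit <- match.arg(unit)
  xyz <- mol$coords
  if (unit == "angstrom") xyz <- xyz / shieldens_constants$bohr_per_angstrom
  lines <- c(sprintf("%d", n_atoms(mol)), comment,
             sprintf("%-3s %20.12f %20.12f %20.12f",
                     mol$element, xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}
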