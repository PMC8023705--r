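# Plane scans and volumetric export of shielding densities.

#' Plane specification for 2-D scans
#'
#' Defines a rectangular lattice in a plane: an origin, two orthonormal
#' in-plane axes, half-extents, a lattice spacing, an offset along the plane
#' normal, and an export clamp range.
#'
#' @param origin Length-3 plane origin (bohr).
#' @param axis1,axis2 In-plane axis vectors; must be orthonormal to 1e-12.
#' @param extent1,extent2 Half-extents along the axes (bohr); the lattice
#'   spans `[-extent, +extent]`.
#' @param spacing Lattice spacing > 0 (bohr).
#' @param offset Displacement along `axis1 x axis2` (bohr), e.g. 1.0 for a
#'   scan one bohr above the base plane.
#' @param clamp Length-2 export clamp range (display only; raw values are
#'   always retained).
#' @return A `plane_spec`.
#' @export
plane_spec <- function(origin = c(0, 0, 0), axis1 = c(1, 0, 0),
                       axis2 = c(0, 1, 0), extent1 = 8, extent2 = 8,
                       spacing = 0.25, offset = 0,
                       clamp = c(-0.2, 0.2)) {
  axis1 <- as.numeric(axis1); axis2 <- as.numeric(axis2)
  if (abs(sum(axis1^2) - 1) > 1e-12 || abs(sum(axis2^2) - 1) > 1e-12 ||
      abs(sum(axis1 * axis2)) > 1e-12) {
    stop("plane axes must be orthonormal (tolerance 1e-12)")
  }
  if (spacing <= 0) stop("plane spacing must be > 0")
  normal <- c(axis1[2] * axis2[3] - axis1[3] * axis2[2],
              axis1[3] * axis2[1] - axis1[1] * axis2[3],
              axis1[1] * axis2[2] - axis1[2] * axis2[1])
  structure(list(origin = as.numeric(origin), axis1 = axis1, axis2 = axis2,
                 normal = normal, extent1 = extent1, extent2 = extent2,
                 spacing = spacing, offset = offset, clamp = sort(clamp)),
            class = "plane_spec")
}

#' Scan a scalar field on a plane
#'
#' Evaluates a field source on the lattice defined by a [plane_spec()].
#' Raw values are retained; the clamp range is applied only in the export
#' channel of [write_plane_csv()].
#'
#' @param field Function `points -> values` (n x 3 matrix in, vector out),
#'   e.g. a closure over [shielding_density()].
#' @param spec A [plane_spec()].
#' @return A `plane_scan`: list with `values` (row-major lattice matrix,
#'   rows along axis1), `u`, `v` (lattice coordinates), `spec`; world
#'   coordinates are `origin + offset*normal + u*axis1 + v*axis2`.
#' @export
plane_scan <- function(field, spec) {
  stopifnot(inherits(spec, "plane_spec"))
  u <- seq(-spec$extent1, spec$extent1, by = spec$spacing)
  v <- seq(-spec$extent2, spec$extent2, by = spec$spacing)
  base <- spec$origin + spec$offset * spec$normal
  G <- expand.grid(u = u, v = v)
  pts <- matrix(base, nrow(G), 3, byrow = TRUE) +
    outer(G$u, spec$axis1) + outer(G$v, spec$axis2)
  vals <- field(pts)
  structure(list(values = matrix(vals, length(u), length(v)),
                 u = u, v = v, points = pts, spec = spec),
            class = "plane_scan")
}

#' Write a plane scan as CSV
#'
#' Column order: `x, y, z, value` (bohr; raw values), plus a `clamped`
#' column holding the values clipped to the spec's clamp range for direct
#' use as a display channel.
#'
#' @param scan A [plane_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plane_csv <- function(scan, path) {
  stopifnot(inherits(scan, "plane_scan"))
  cl <- scan$spec$clamp
  v <- as.vector(scan$values)
  df <- data.frame(x = scan$points[, 1], y = scan$points[, 2],
                   z = scan$points[, 3], value = v,
                   clamped = pmin(cl[2], pmax(cl[1], v)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a scalar lattice as a Gaussian cube file
#'
#' Standard cube dialect: two comment lines, atom-count line with lattice
#' origin, three axis lines (voxel counts and step vectors, bohr), one line
#' per atom (charge and position), then the values with the third axis
#' fastest. Raw values are stored; any clamp range or isovalue belongs in
#' the comment metadata, not the data.
#'
#' @param values n1 x n2 x n3 array of values on an axis-aligned lattice.
#' @param origin Length-3 lattice origin (bohr).
#' @param spacing Length-3 voxel spacing (bohr); must be uniform per axis.
#' @param mol A [molecule()] written into the atom block.
#' @param path Output path.
#' @param comment Comment metadata for the header lines.
#' @return `path`, invisibly.
#' @export
write_cube <- function(values, origin, spacing, mol, path,
                       comment = "shielding density") {
  dm <- dim(values)
  if (length(dm) != 3L) stop("values must be a 3-d array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("non-uniform or invalid spacing: supply one positive step per axis")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, "shieldens cube export (bohr, z-fastest)"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", n_atoms(mol),
                     origin[1], origin[2], origin[3]), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", dm[1], spacing[1], 0, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", dm[2], 0, spacing[2], 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", dm[3], 0, 0, spacing[3]), con)
  for (i in seq_len(n_atoms(mol))) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", mol$charge[i],
                       as.numeric(mol$charge[i]), mol$coords[i, 1],
                       mol$coords[i, 2], mol$coords[i, 3]), con)
  }
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
    row <- values[i, j, ]
    for (s in seq(1, length(row), by = 6)) {
      e <- min(s + 5, length(row))
      writeLines(paste(sprintf("%13.5E", row[s:e]), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a Gaussian cube file written by [write_cube()]
#'
#' @param path Path to the cube file.
#' @return List with `values` (n1 x n2 x n3), `origin`, `spacing`,
#'   `molecule`, `comment`.
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  comment <- lines[1]
  hd <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  h3 <- hd(lines[3]); nat <- as.integer(h3[1]); origin <- h3[2:4]
  ax <- lapply(4:6, function(i) hd(lines[i]))
  dm <- vapply(ax, function(a) as.integer(a[1]), integer(1))
  spacing <- c(ax[[1]][2], ax[[2]][3], ax[[3]][4])
  atoms <- t(vapply(seq_len(nat), function(i) hd(lines[6 + i]), numeric(5)))
  z <- as.integer(atoms[, 1])
  sym <- names(.element_z)[match(z, .element_z)]
  mol <- molecule(sym, atoms[, 3:5, drop = FALSE])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:(6 + nat))]), "\\s+")))
  if (length(vals) != prod(dm)) {
    stop(sprintf("cube value count %d does not match header voxel count %d",
                 length(vals), prod(dm)))
  }
  # stored z-fastest: fill a dm[3] x dm[2] x dm[1] array then transpose
  arr <- aperm(array(vals, rev(dm)), c(3, 2, 1))
  list(values = arr, origin = origin, spacing = spacing, molecule = mol,
       comment = comment)
}
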