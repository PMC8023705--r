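# Assembly of per-atom molecular integration grids.

#' Build per-atom molecular grids
#'
#' Builds one atomic grid per atom: Lindh-style radial nodes times a
#' Lebedev-type angular grid, with Becke fuzzy-cell weights folded in. The
#' union of the atomic grids integrates smooth, rapidly decaying functions
#' over all space; each atomic grid integrates the function over that atom's
#' fuzzy Becke cell, and the decomposition is exact by construction
#' (partition of unity), leaving only quadrature error.
#'
#' @param mol A [molecule()].
#' @param radial_accuracy Relative accuracy of the radial rule
#'   (see [radial_grid()]).
#' @param angular_order Lebedev-type point count (see [lebedev_orders()]);
#'   fixed per atom, no radial pruning.
#' @param becke A [becke_spec()].
#' @param basis Optional list of [gaussian_shell()]s; when given, each
#'   atom's radial exponent range is taken from its shells instead of the
#'   element table.
#' @param lmax Largest angular momentum assumed in the radial error model.
#' @return A list of `atomic_grid` objects: `owner` (atom index), `points`
#'   (m x 3, bohr), `weights` (bohr^3, radial x angular x Becke).
#' @export
build_grids <- function(mol, radial_accuracy = 1e-12, angular_order = 194,
                        becke = becke_spec(), basis = NULL, lmax = 3L) {
  ang <- lebedev_grid(angular_order)
  nat <- n_atoms(mol)
  grids <- vector("list", nat)
  for (i in seq_len(nat)) {
    if (!is.null(basis)) {
      ex <- unlist(lapply(basis, function(s)
        if (s$center == i) s$exponents else NULL))
      if (length(ex) == 0L) {
        stop("atom ", i, " has no shells; cannot derive its radial range from the basis")
      }
      rg <- radial_grid(accuracy = radial_accuracy, alpha_min = min(ex),
                        alpha_max = max(ex), lmax = lmax)
    } else {
      rg <- radial_grid(element = mol$element[i], accuracy = radial_accuracy,
                        lmax = lmax)
    }
    npt <- length(rg$r) * nrow(ang$points)
    pts <- matrix(0, npt, 3)
    w0 <- numeric(npt)
    row <- 1L
    for (k in seq_along(rg$r)) {
      blk <- row:(row + nrow(ang$points) - 1L)
      pts[blk, ] <- sweep(ang$points * rg$r[k], 2, mol$coords[i, ], "+")
      w0[blk] <- rg$w[k] * ang$weights * 4 * pi
      row <- row + nrow(ang$points)
    }
    grids[[i]] <- structure(list(owner = i, points = pts, weights = w0),
                            class = "atomic_grid")
  }
  # fold in Becke weights (all-points pass, chunked)
  if (nat > 1L) {
    for (i in seq_len(nat)) {
      W <- becke_weights(grids[[i]]$points, mol, becke)
      grids[[i]]$weights <- grids[[i]]$weights * W[, i]
    }
  }
  grids
}

#' @export
print.atomic_grid <- function(x, ...) {
  cat(sprintf("<atomic_grid: owner %d, %d points>\n", x$owner,
              nrow(x$points)))
  invisible(x)
}

#' Integrate a scalar field over grids
#'
#' @param grids List of `atomic_grid` objects from [build_grids()].
#' @param f Function `points -> values` (vectorized over rows).
#' @return Sum of the weighted values over all atomic grids.
#' @export
grid_integrate <- function(grids, f) {
  sum(vapply(grids, function(g) sum(g$weights * f(g$points)), numeric(1)))
}

#' Dump grids to a plain text file
#'
#' Columnar text, one point per line: `x y z w` in bohr (bohr^3 for w),
#' preceded by comment lines marking each atomic block. Intended for
#' debugging and external inspection.
#'
#' @param grids List of `atomic_grid` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grids, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in grids) {
    writeLines(sprintf("# atom %d  n %d", g$owner, nrow(g$points)), con)
    writeLines(sprintf("%.17g %.17g %.17g %.17g", g$points[, 1],
                       g$points[, 2], g$points[, 3], g$weights), con)
  }
  invisible(path)
}

#' Load grids dumped by [write_grid()]
#'
#' @param path Path to the text dump.
#' @return List of `atomic_grid` objects.
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# atom ", lines)
  if (length(hdr) == 0L) stop("not a grid dump: ", path)
  grids <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    owner <- as.integer(strsplit(lines[hdr[i]], "\\s+")[[1]][3])
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    m <- matrix(as.numeric(unlist(strsplit(block, " "))), ncol = 4,
                byrow = TRUE)
    grids[[i]] <- structure(list(owner = owner, points = m[, 1:3],
                                 weights = m[, 4]), class = "atomic_grid")
  }
  grids
}
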