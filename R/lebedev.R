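# Lebedev-type angular quadrature on the unit sphere.
#
# Grids are octahedrally symmetric point sets built from the classical orbit
# types (vertex, edge-midpoint, face, and the three parametric orbit
# families). The orbit parameters and weights in R/lebedev_data.R were
# solved once from the spherical moment equations (see
# data-raw/lebedev-solve.R) and are frozen here; each grid integrates every
# spherical harmonic up to its algebraic degree to round-off. Weights follow
# the unit-measure convention (they sum to 1) and are multiplied by 4 pi
# when molecular grids are assembled.

.leb_images <- function(v) {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  M <- NULL
  for (p in seq_len(6)) {
    vp <- v[perms[p, ]]
    M <- rbind(M, signs * matrix(vp, 8, 3, byrow = TRUE))
  }
  M[!duplicated(round(M, 12)), , drop = FALSE]
}

.leb_orbit_points <- function(orbit) {
  switch(orbit$type,
    a1 = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1)),
    a2 = .leb_images(c(1 / sqrt(2), 1 / sqrt(2), 0)),
    a3 = matrix(1 / sqrt(3), 8, 3) *
      as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1))),
    b = .leb_images(c(orbit$a, orbit$a, sqrt(max(0, 1 - 2 * orbit$a^2)))),
    c = .leb_images(c(orbit$a, sqrt(max(0, 1 - orbit$a^2)), 0)),
    d = .leb_images(c(orbit$a, orbit$b,
                      sqrt(max(0, 1 - orbit$a^2 - orbit$b^2)))),
    stop("unknown orbit type: ", orbit$type))
}

#' Supported angular grid sizes
#'
#' @return Integer vector of supported Lebedev-type point counts, in
#'   increasing order of algebraic degree.
#' @export
lebedev_orders <- function() {
  as.integer(names(.lebedev_params))
}

#' Lebedev-type angular grid
#'
#' Returns unit-sphere nodes and weights for one of the supported orders
#' (identified by point count). Weights sum to 1; the grid integrates all
#' spherical harmonics up to the order's algebraic degree to round-off.
#'
#' @param order Point count of the grid (see [lebedev_orders()]).
#' @return A list with `points` (n x 3 unit vectors), `weights`
#'   (unit-measure, summing to 1) and `degree` (algebraic degree).
#' @export
lebedev_grid <- function(order) {
  key <- as.character(as.integer(order))
  par <- .lebedev_params[[key]]
  if (is.null(par)) {
    stop("unsupported angular order ", order, "; supported orders: ",
         paste(lebedev_orders(), collapse = ", "))
  }
  pts <- NULL; wts <- NULL
  for (orbit in par$orbits) {
    P <- .leb_orbit_points(orbit)
    pts <- rbind(pts, P)
    wts <- c(wts, rep(orbit$w, nrow(P)))
  }
  stopifnot(nrow(pts) == as.integer(key))
  list(points = pts, weights = wts, degree = par$degree)
}
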