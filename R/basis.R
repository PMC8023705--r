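# Gaussian basis shells and AO evaluation.

#' Create a contracted Gaussian shell
#'
#' A shell of 2l+1 solid-harmonic atomic orbitals sharing one radial
#' contraction. Primitives are normalized spherical Gaussians
#' `N_l(zeta) r^l Y_lm exp(-zeta r^2)`; contraction coefficients multiply the
#' normalized primitives and are used as given (no automatic renormalization
#' of the contraction -- engine adapters are responsible for converting their
#' conventions, see [adapt_engine()]).
#'
#' @param center Index of the atom (in the owning molecule) the shell sits on.
#' @param l Angular momentum (0 = s, 1 = p, ...; 0..6 supported).
#' @param exponents Strictly positive primitive exponents, sorted descending.
#' @param coefficients Contraction coefficients, one per exponent.
#' @param pure Solid-harmonic flag. Only `TRUE` is supported; Cartesian
#'   shells must be transformed to the solid-harmonic convention by the
#'   engine adapter.
#' @return An object of class `gaussian_shell`.
#' @export
gaussian_shell <- function(center, l, exponents, coefficients, pure = TRUE) {
  if (!isTRUE(pure)) {
    stop("Cartesian shells are not supported; convert to solid-harmonic AOs in the adapter")
  }
  if (length(exponents) < 1L) stop("a shell needs at least one primitive")
  if (any(exponents <= 0)) stop("shell exponents must be strictly positive")
  if (is.unsorted(rev(exponents), strictly = FALSE)) {
    stop("shell exponents must be sorted in descending order")
  }
  if (length(coefficients) != length(exponents)) {
    stop("one contraction coefficient per exponent required")
  }
  if (l > 6 || l < 0 || l != round(l)) {
    stop("unsupported angular momentum l = ", l, " (supported: 0..6)")
  }
  structure(
    list(center = as.integer(center), l = as.integer(l),
         exponents = as.numeric(exponents),
         coefficients = as.numeric(coefficients), pure = TRUE),
    class = "gaussian_shell")
}

# radial normalization of a spherical Gaussian primitive:
# integral of [N r^l exp(-zeta r^2)]^2 r^2 dr = 1
.primitive_norm <- function(l, zeta) {
  sqrt(2 * (2 * zeta)^(l + 1.5) / gamma(l + 1.5))
}

#' Number of atomic orbitals spanned by a shell list
#' @param shells List of [gaussian_shell()] objects.
#' @return Integer AO dimension (solid-harmonic counting, 2l+1 per shell).
#' @export
n_ao <- function(shells) sum(vapply(shells, function(s) 2L * s$l + 1L, integer(1)))

#' Evaluate atomic orbitals and their gradients
#'
#' Evaluates every contracted solid-harmonic AO and its Cartesian gradient at
#' a set of points. AO ordering is the canonical one: shells in input order,
#' within a shell m = -l..l.
#'
#' @param shells List of [gaussian_shell()] objects.
#' @param mol The owning [molecule()] (supplies shell centers).
#' @param points n x 3 matrix of positions (bohr).
#' @return A list with `values` (n x nao), `dx`, `dy`, `dz` (n x nao
#'   gradients), and `ao` (data frame: shell, center, l, m per AO).
#' @export
eval_ao <- function(shells, mol, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (!all(is.finite(points))) stop("evaluation points must be finite")
  n <- nrow(points)
  nao <- n_ao(shells)
  V <- matrix(0, n, nao); Dx <- matrix(0, n, nao)
  Dy <- matrix(0, n, nao); Dz <- matrix(0, n, nao)
  ao_shell <- integer(nao); ao_center <- integer(nao)
  ao_l <- integer(nao); ao_m <- integer(nao)
  col <- 0L
  for (si in seq_along(shells)) {
    sh <- shells[[si]]
    R <- mol$coords[sh$center, ]
    x <- points[, 1] - R[1]; y <- points[, 2] - R[2]; z <- points[, 3] - R[3]
    r2 <- x^2 + y^2 + z^2
    rad <- numeric(n); drad <- numeric(n)   # radial part and d(rad)/d(r^2)
    for (p in seq_along(sh$exponents)) {
      zeta <- sh$exponents[p]
      t <- sh$coefficients[p] * .primitive_norm(sh$l, zeta) * exp(-zeta * r2)
      rad <- rad + t
      drad <- drad - zeta * t
    }
    polys <- solid_harmonics(sh$l, "sphere")
    for (mi in seq_along(polys)) {
      P <- polys[[mi]]
      s <- .poly_eval(P, x, y, z)
      col <- col + 1L
      V[, col] <- s * rad
      Dx[, col] <- .poly_eval(.poly_deriv(P, 1), x, y, z) * rad + s * drad * 2 * x
      Dy[, col] <- .poly_eval(.poly_deriv(P, 2), x, y, z) * rad + s * drad * 2 * y
      Dz[, col] <- .poly_eval(.poly_deriv(P, 3), x, y, z) * rad + s * drad * 2 * z
      ao_shell[col] <- si; ao_center[col] <- sh$center
      ao_l[col] <- sh$l; ao_m[col] <- mi - sh$l - 1L
    }
  }
  list(values = V, dx = Dx, dy = Dy, dz = Dz,
       ao = data.frame(shell = ao_shell, center = ao_center,
                       l = ao_l, m = ao_m))
}

#' Analytic overlap matrix of a solid-harmonic Gaussian basis
#'
#' Overlap integrals evaluated by high-accuracy numerical quadrature on the
#' package's own molecular grids; intended for constructing and validating
#' small synthetic response bundles, not for production electronic structure.
#'
#' @param shells List of [gaussian_shell()] objects.
#' @param mol The owning [molecule()].
#' @param radial_accuracy,angular_order Grid controls, see [build_grids()].
#' @return nao x nao overlap matrix.
#' @export
overlap_matrix <- function(shells, mol, radial_accuracy = 1e-12,
                           angular_order = 194) {
  grids <- build_grids(mol, radial_accuracy = radial_accuracy,
                       angular_order = angular_order, basis = shells)
  nao <- n_ao(shells)
  S <- matrix(0, nao, nao)
  for (g in grids) {
    ao <- eval_ao(shells, mol, g$points)
    S <- S + crossprod(ao$values * g$weights, ao$values)
  }
  (S + t(S)) / 2
}
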