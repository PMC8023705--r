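# Exponential-type radial quadrature in the spirit of Lindh, Malmqvist and
# Gagliardi: a trapezoidal rule on an exponentially mapped coordinate,
# r_k = c (e^{k h} - 1), with the step h, the innermost node and the
# outermost node all derived from a single requested relative accuracy and
# the Gaussian exponent range the grid must integrate.
#
# The step is fixed by the discretization error of the trapezoidal rule for
# integrands r^{2l+2} e^{-a r^2} on the pure exponential map r = e^x, which
# is scale invariant: by Poisson summation the leading relative error is
#   eps(h) = 2 |Gamma(l + 3/2 + i pi / h)| / Gamma(l + 3/2),
# independent of the exponent a. |Gamma| on the complex line is evaluated
# from |Gamma(1/2 + iy)|^2 = pi / cosh(pi y) by upward recurrence. The
# outer cutoff comes from the tail of the most diffuse integrand (an upper
# incomplete gamma), the inner cutoff from the small-r truncation error of
# the steepest one.

# |Gamma(l + 3/2 + iy)| for integer l >= 0
.abs_gamma_half <- function(l, y) {
  v <- sqrt(pi / cosh(pi * y))           # |Gamma(1/2 + iy)|
  a <- 0.5
  for (j in seq_len(l + 1)) {            # recurrence up to l + 3/2
    v <- v * sqrt(a^2 + y^2)
    a <- a + 1
  }
  v
}

.lmg_step <- function(accuracy, lmax) {
  f <- function(h) {
    max(vapply(0:lmax, function(l) {
      2 * .abs_gamma_half(l, pi / h) / gamma(l + 1.5)
    }, numeric(1))) - accuracy
  }
  stats::uniroot(f, c(1e-3, 2), tol = 1e-12)$root
}

#' Radial quadrature grid
#'
#' Builds the exponential-type radial grid for one element (or an explicit
#' Gaussian exponent range). Nodes and weights integrate
#' `f(r) r^2 dr` on `(0, Inf)`; the weights include the `r^2` volume factor.
#'
#' @param element Element symbol used to look up a default Gaussian exponent
#'   range (H..Ne table); ignored when `alpha_min`/`alpha_max` are given.
#' @param accuracy Requested relative accuracy (default 1e-12); the node
#'   count grows as the accuracy is tightened.
#' @param alpha_min Most diffuse Gaussian exponent the grid must integrate
#'   (scalar or vector indexed by l = 0, 1, ... for l-dependent ranges).
#' @param alpha_max Steepest Gaussian exponent.
#' @param lmax Largest angular momentum carried by the radial integrands.
#' @return A list with `r` (strictly increasing nodes, bohr) and `w`
#'   (positive weights including the `r^2` factor, bohr^3).
#' @export
radial_grid <- function(element = NULL, accuracy = 1e-12, alpha_min = NULL,
                        alpha_max = NULL, lmax = 2L) {
  if (is.null(alpha_min) || is.null(alpha_max)) {
    if (is.null(element) || is.null(.radial_alpha_defaults[[element]])) {
      stop("no default exponent range for element: ",
           if (is.null(element)) "<none>" else element,
           " (supply alpha_min and alpha_max)")
    }
    ab <- .radial_alpha_defaults[[element]]
    alpha_min <- alpha_min %||% ab[1]
    alpha_max <- alpha_max %||% ab[2]
  }
  if (!(accuracy > 0 && accuracy < 1e-2)) {
    stop("radial accuracy must be in (0, 1e-2)")
  }
  h <- .lmg_step(accuracy, lmax)
  # outer cutoff: tail of the most diffuse integrand, per l
  r_out <- max(vapply(seq_along(alpha_min) - 1L, function(l) {
    am <- alpha_min[l + 1L]
    sqrt(stats::qgamma(accuracy, shape = min(l, lmax) + 1.5,
                       lower.tail = FALSE) / am)
  }, numeric(1)))
  # inner cutoff: small-r truncation of the steepest (product) integrand
  r_in <- sqrt(stats::qgamma(accuracy, shape = 1.5) / (2 * max(alpha_max)))
  cc <- r_in / (exp(h) - 1)
  n <- ceiling(log(1 + r_out / cc) / h)
  k <- seq_len(n)
  r <- cc * (exp(k * h) - 1)
  w <- h * (r + cc) * r^2
  list(r = r, w = w, h = h, n = n)
}
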