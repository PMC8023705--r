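# Analytic current-density models: ring currents and atomic vortices.
#
# These providers have closed-form Biot-Savart answers and serve as
# engine-free oracles for the kernel, the grids and the unit conversions,
# as well as qualitative stand-ins for the ring-current topology of
# aromatic and antiaromatic hydrocarbons.

#' Ring-current loop model
#'
#' A toroidal current-density derivative field: circulation around the loop
#' axis with a Gaussian cross-section profile in the (in-plane radius,
#' height) half-plane. The field responds linearly to the component of the
#' external field along the loop normal, and is divergence-free by
#' construction (purely azimuthal with axisymmetric magnitude). A diatropic
#' loop circulates so that its induced field at the loop center opposes the
#' external field (the aromatic signature); a paratropic loop reinforces it.
#'
#' The total circulating current per unit field is `strength` (a.u.): the
#' Gaussian cross-section is normalized over the half-plane, so in the
#' thin-profile limit the model approaches an ideal current loop of radius
#' `radius` carrying the current derivative `strength`.
#'
#' @param center Length-3 loop center (bohr).
#' @param normal Length-3 loop axis (normalized internally).
#' @param radius Loop radius R > 0 (bohr).
#' @param strength Circulation strength per unit field (a.u.), > 0.
#' @param width Gaussian cross-section standard deviation w > 0 (bohr).
#' @param tropicity `"diatropic"` or `"paratropic"`.
#' @return A `loop_model` specification.
#' @export
loop_model <- function(center = c(0, 0, 0), normal = c(0, 0, 1), radius,
                       strength = 1, width, tropicity = c("diatropic",
                                                          "paratropic")) {
  tropicity <- match.arg(tropicity)
  if (radius <= 0 || width <= 0) stop("loop radius and width must be > 0")
  nrm <- sqrt(sum(normal^2))
  if (nrm < 1e-14) stop("loop normal must be nonzero")
  structure(list(center = as.numeric(center), normal = as.numeric(normal) / nrm,
                 radius = radius, strength = strength, width = width,
                 tropicity = tropicity), class = "loop_model")
}

#' Provider for a ring-current loop model
#'
#' @param model A [loop_model()].
#' @return A [current_provider()] returning the toroidal Gaussian-profile
#'   current derivative field.
#' @export
make_loop_provider <- function(model) {
  stopifnot(inherits(model, "loop_model"))
  n <- model$normal
  # in-plane orthonormal frame
  aux <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- aux - sum(aux * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  sgn <- if (model$tropicity == "diatropic") -1 else 1
  # half-plane normalized Gaussian cross-section
  norm2d <- 1 / (2 * pi * model$width^2)
  fun <- function(points, beta) {
    points <- matrix(as.numeric(points), ncol = 3)
    rel <- sweep(points, 2, model$center)
    z <- rel %*% n
    x1 <- rel %*% e1; x2 <- rel %*% e2
    s <- sqrt(x1^2 + x2^2)
    prof <- norm2d * exp(-((s - model$radius)^2 + z^2) / (2 * model$width^2))
    # azimuthal unit vector (zero where s ~ 0)
    inv <- ifelse(s > 1e-300, 1 / s, 0)
    phihat <- (-x2 * inv) %*% t(e1) + (x1 * inv) %*% t(e2)
    sgn * model$strength * n[beta] * as.numeric(prof) * phihat
  }
  current_provider(fun)
}

#' Atomic vortex model
#'
#' The Larmor (diamagnetic) current-density derivative of a spherical
#' charge density centered at a point:
#' `dJ/dB_beta = -1/2 rho(|r - c|) (e_beta x (r - c))`.
#' The density is a normalized single Gaussian carrying `n_electrons`
#' electrons; the isotropic shielding at the vortex center obeys the Lamb
#' formula `alpha^2/3 <1/r>`.
#'
#' @param center Length-3 vortex center (bohr).
#' @param exponent Gaussian density exponent a, i.e.
#'   `rho(r) = n_electrons (a/pi)^(3/2) exp(-a r^2)`.
#' @param n_electrons Electron count of the density.
#' @return A `vortex_model` specification.
#' @export
vortex_model <- function(center = c(0, 0, 0), exponent = 2, n_electrons = 1) {
  if (exponent <= 0) stop("vortex density exponent must be > 0")
  structure(list(center = as.numeric(center), exponent = exponent,
                 n_electrons = n_electrons), class = "vortex_model")
}

#' Provider for an atomic vortex model
#'
#' @param model A [vortex_model()].
#' @return A [current_provider()] realizing the Larmor diamagnetic current.
#' @export
make_vortex_provider <- function(model) {
  stopifnot(inherits(model, "vortex_model"))
  a <- model$exponent
  c0 <- model$center
  amp <- model$n_electrons * (a / pi)^1.5
  fun <- function(points, beta) {
    points <- matrix(as.numeric(points), ncol = 3)
    rel <- sweep(points, 2, c0)
    rho <- amp * exp(-a * rowSums(rel^2))
    e <- c(0, 0, 0); e[beta] <- 1
    cross <- cbind(e[2] * rel[, 3] - e[3] * rel[, 2],
                   e[3] * rel[, 1] - e[1] * rel[, 3],
                   e[1] * rel[, 2] - e[2] * rel[, 1])
    -0.5 * rho * cross
  }
  current_provider(fun)
}

#' Sum of providers
#'
#' @param ... [current_provider()] objects.
#' @return A provider returning the superposition of the fields.
#' @export
provider_sum <- function(...) {
  ps <- list(...)
  current_provider(function(points, beta) {
    Reduce(`+`, lapply(ps, function(p) p(points, beta)))
  })
}

#' Benzene-like composite ring-current model
#'
#' A qualitative superposition emulating the current-density topology of an
#' aromatic six-membered ring: a diatropic perimeter loop, a weaker
#' paratropic loop inside the ring, and a diamagnetic atomic vortex on each
#' of the six ring positions. It reproduces the sign topology of shielding
#' density maps (shielding band outside the ring, near/far-side asymmetries
#' from the inner paratropic loop) and is intended for visualization smoke
#' tests only -- it is a model, never compared against ab initio numbers.
#'
#' @param ring_radius Carbon ring radius (bohr).
#' @param perimeter_strength Diatropic perimeter loop strength (a.u.).
#' @param inner_strength Paratropic inner loop strength (a.u.).
#' @param include_inner Include the paratropic inner loop.
#' @param include_vortices Include per-atom vortices.
#' @return A list with `provider` (a [current_provider()]), the component
#'   models, and `molecule` (six pseudo-carbon ring positions).
#' @export
benzene_like_composite <- function(ring_radius = 2.63,
                                   perimeter_strength = 1,
                                   inner_strength = 0.35,
                                   include_inner = TRUE,
                                   include_vortices = TRUE) {
  ang <- 2 * pi * (0:5) / 6
  ring <- cbind(ring_radius * cos(ang), ring_radius * sin(ang), 0)
  mol <- molecule(rep("C", 6), ring)
  parts <- list(make_loop_provider(loop_model(
    radius = ring_radius + 0.9, strength = perimeter_strength, width = 0.9,
    tropicity = "diatropic")))
  if (include_inner) {
    parts <- c(parts, list(make_loop_provider(loop_model(
      radius = ring_radius * 0.45, strength = inner_strength, width = 0.7,
      tropicity = "paratropic"))))
  }
  if (include_vortices) {
    for (i in 1:6) {
      parts <- c(parts, list(make_vortex_provider(
        vortex_model(center = ring[i, ], exponent = 3, n_electrons = 2))))
    }
  }
  list(provider = do.call(provider_sum, parts), molecule = mol,
       ring_radius = ring_radius)
}

#' Minimal synthetic response bundle
#'
#' Builds a small 1- or 2-center s-type bundle with chosen density and
#' perturbed density matrices, as a hand-checkable unit-test surface for the
#' CDT evaluation. The overlap matrix is computed on the package's own
#' grids; all bundle invariants are enforced.
#'
#' @param centers m x 3 matrix of s-shell centers (bohr), one shell each.
#' @param exponents Length-m primitive exponents.
#' @param density m x m symmetric density matrix.
#' @param perturbed List of three m x m antisymmetric matrices
#'   (default: all zero -- a purely diamagnetic bundle).
#' @param element Element symbol(s) for the pseudo-atoms (default "He").
#' @return A validated [response_bundle()].
#' @export
make_min_bundle <- function(centers, exponents, density, perturbed = NULL,
                            element = "He") {
  centers <- matrix(as.numeric(centers), ncol = 3)
  m <- nrow(centers)
  if (length(exponents) != m) stop("one exponent per center required")
  mol <- molecule(rep_len(element, m), centers)
  shells <- lapply(seq_len(m), function(i)
    gaussian_shell(i, 0L, exponents[i], 1.0))
  if (is.null(perturbed)) {
    perturbed <- replicate(3, matrix(0, m, m), simplify = FALSE)
  }
  # closed-form overlap of normalized s Gaussians
  S <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    zi <- exponents[i]; zj <- exponents[j]
    d2 <- sum((centers[i, ] - centers[j, ])^2)
    S[i, j] <- (2 * sqrt(zi * zj) / (zi + zj))^1.5 *
      exp(-zi * zj / (zi + zj) * d2)
  }
  nel <- sum(diag(as.matrix(density) %*% S))
  response_bundle(mol, shells, S, density, perturbed, nel,
                  metadata = list(method = "synthetic minimal bundle"))
}
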