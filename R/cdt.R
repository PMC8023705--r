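# Current-density susceptibility tensor (CDT) from GIAO density matrices.
#
# The implemented expression (derived step by step in the methods vignette)
# for the
# derivative of the induced current density with respect to the external
# field, for a closed-shell density matrix D and perturbed matrices
# P^beta = Im(dD/dB_beta) over real solid-harmonic AOs chi_mu with centers
# R_mu, is
#
#   dJ_alpha/dB_beta (r) =
#       - sum_{mu nu} P^beta_{mu nu} chi_mu(r) d_alpha chi_nu(r)
#     + 1/2 sum_{mu nu} D_{mu nu} [(R_nu - R_mu) x r]_beta
#                         chi_mu(r) d_alpha chi_nu(r)
#     - 1/2 eps_{alpha beta gamma}
#           sum_{mu nu} D_{mu nu} chi_mu(r) chi_nu(r) (r - R_nu)_gamma
#
# The three terms are the paramagnetic response, the London-phase transfer
# term, and the diamagnetic term. Every occurrence of the gauge origin
# cancels exactly in this form: no gauge-origin parameter exists anywhere in
# the evaluation.

.eps3 <- local({
  e <- array(0, c(3, 3, 3))
  e[1, 2, 3] <- e[2, 3, 1] <- e[3, 1, 2] <- 1
  e[3, 2, 1] <- e[1, 3, 2] <- e[2, 1, 3] <- -1
  e
})

#' Evaluate the current-density susceptibility tensor
#'
#' Evaluates the full 3 x 3 derivative tensor `T[alpha, beta] =
#' dJ_alpha/dB_beta` (atomic units) of the magnetically induced current
#' density at arbitrary points, from the density and perturbed density
#' matrices of a GIAO calculation. The expression is free of any gauge
#' origin by construction.
#'
#' @param bundle A validated [response_bundle()].
#' @param points n x 3 matrix of positions (bohr).
#' @param chunk Number of points evaluated per block (bounds the working
#'   set for large point sets).
#' @return A `cdt_sample`: list with `points` and `tensor`
#'   (n x 3 x 3 array, `tensor[p, alpha, beta]`).
#' @export
eval_cdt <- function(bundle, points, chunk = 20000L) {
  points <- matrix(as.numeric(points), ncol = 3)
  nao <- n_ao(bundle$shells)
  if (nrow(bundle$density) != nao) {
    stop("AO dimension mismatch between bundle matrices and shells")
  }
  n <- nrow(points)
  Tfull <- array(0, c(n, 3, 3))
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  for (ii in idx) {
    Tfull[ii, , ] <- .eval_cdt_block(bundle, points[ii, , drop = FALSE])
  }
  if (!all(is.finite(Tfull))) stop("non-finite CDT values encountered")
  structure(list(points = points, tensor = Tfull), class = "cdt_sample")
}

.eval_cdt_block <- function(bundle, pts) {
  n <- nrow(pts)
  ao <- eval_ao(bundle$shells, bundle$molecule, pts)
  V <- ao$values
  G <- list(ao$dx, ao$dy, ao$dz)
  Rc <- bundle$molecule$coords[ao$ao$center, , drop = FALSE]  # nao x 3
  D <- bundle$density
  Tb <- array(0, c(n, 3, 3))

  VD <- V %*% D
  rho <- rowSums(VD * V)
  # M[, gamma] = sum_{mu nu} D chi_mu chi_nu (R_nu)_gamma
  # NG[[gamma]][, alpha] = sum D (R_nu)_gamma chi_mu d_alpha chi_nu
  # OG[[gamma]][, alpha] = sum D (R_mu)_gamma chi_mu d_alpha chi_nu
  M <- matrix(0, n, 3)
  NG <- OG <- vector("list", 3)
  for (g in 1:3) {
    Dg <- sweep(D, 2, Rc[, g], "*")
    VDg <- V %*% Dg
    M[, g] <- rowSums(VDg * V)
    Vg <- sweep(V, 2, Rc[, g], "*")
    VgD <- Vg %*% D
    NG[[g]] <- vapply(1:3, function(a) rowSums(VDg * G[[a]]), numeric(n))
    OG[[g]] <- vapply(1:3, function(a) rowSums(VgD * G[[a]]), numeric(n))
  }
  # paramagnetic
  for (b in 1:3) {
    A <- V %*% bundle$perturbed_density[[b]]
    for (a in 1:3) Tb[, a, b] <- -rowSums(A * G[[a]])
  }
  for (a in 1:3) for (b in 1:3) {
    acc <- numeric(n)
    for (g in 1:3) {
      # diamagnetic: -1/2 eps_{a b g} (rho r_g - M_g)
      if (.eps3[a, b, g] != 0) {
        acc <- acc - 0.5 * .eps3[a, b, g] * (rho * pts[, g] - M[, g])
      }
      # London transfer: +1/2 eps_{b g d} r_d (NG - OG)
      for (d in 1:3) {
        if (.eps3[b, g, d] != 0) {
          acc <- acc + 0.5 * .eps3[b, g, d] * pts[, d] *
            (NG[[g]][, a] - OG[[g]][, a])
        }
      }
    }
    Tb[, a, b] <- Tb[, a, b] + acc
  }
  Tb
}

#' Wrap a current-density source as a provider
#'
#' A provider is the contract every current-density source satisfies: a
#' callable `f(points, beta)` returning the n x 3 field
#' `J^(beta)(r) = dJ/dB_beta` (the derivative field -- linear response, not a
#' finite-field current) at the given points for a unit field along Cartesian
#' direction `beta` (1 = x, 2 = y, 3 = z).
#'
#' @param fun Function `(points, beta) -> n x 3 matrix`.
#' @param tensor_fun Optional function `(points) -> n x 3 x 3 array` giving
#'   all three field directions in one pass (used for efficiency; derived
#'   from `fun` when omitted).
#' @return An object of class `current_provider` (callable).
#' @export
current_provider <- function(fun, tensor_fun = NULL) {
  if (is.null(tensor_fun)) {
    tensor_fun <- function(points) {
      points <- matrix(as.numeric(points), ncol = 3)
      out <- array(0, c(nrow(points), 3, 3))
      for (b in 1:3) out[, , b] <- fun(points, b)
      out
    }
  }
  structure(fun, tensor_fun = tensor_fun, class = c("current_provider",
                                                    "function"))
}

#' Provider view of a response bundle
#'
#' @param bundle A validated [response_bundle()].
#' @param chunk Chunk size passed to [eval_cdt()].
#' @return A [current_provider()] evaluating the bundle's CDT.
#' @export
bundle_provider <- function(bundle, chunk = 20000L) {
  tensor_fun <- function(points) eval_cdt(bundle, points, chunk = chunk)$tensor
  current_provider(
    function(points, beta) tensor_fun(points)[, , beta, drop = TRUE],
    tensor_fun = tensor_fun)
}

.provider_tensor <- function(provider, points) {
  tf <- attr(provider, "tensor_fun")
  if (!is.null(tf)) return(tf(points))
  points <- matrix(as.numeric(points), ncol = 3)
  out <- array(0, c(nrow(points), 3, 3))
  for (b in 1:3) out[, , b] <- provider(points, b)
  out
}

#' Central-difference divergence of a provider field
#'
#' Estimates `div(dJ/dB_beta)` at a point by second-order central
#' differences; the induced current of a charge-conserving state is
#' solenoidal, so the residual is a numerical sanity check on any provider.
#'
#' @param provider A [current_provider()].
#' @param point Length-3 position (bohr).
#' @param h Stencil spacing (bohr).
#' @return Numeric vector of 3 residuals, one per field direction beta.
#' @export
divergence_residual <- function(provider, point, h = 1e-4) {
  point <- as.numeric(point)
  res <- numeric(3)
  for (b in 1:3) {
    s <- 0
    for (a in 1:3) {
      e <- c(0, 0, 0); e[a] <- h
      Jp <- provider(matrix(point + e, 1), b)
      Jm <- provider(matrix(point - e, 1), b)
      s <- s + (Jp[1, a] - Jm[1, a]) / (2 * h)
    }
    res[b] <- s
  }
  res
}
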