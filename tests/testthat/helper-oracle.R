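# Independent oracles used across the test suite.
#
# oracle_cdt(): slow finite-field evaluation of the current-density
# susceptibility tensor. It builds the full complex field-dependent
# current density from explicitly phase-carrying GIAOs at small finite
# magnetic fields and differentiates numerically (4th-order central
# differences). It carries an explicit gauge origin; the analytic
# implementation has none, so agreement at random gauge origins checks the
# gauge-origin cancellation as well as every term of the analytic
# expression. No code is shared with eval_cdt() beyond the AO evaluator.

# full complex current density at finite field B with gauge origin R_O
.oracle_current_finite <- function(bundle, points, B, R_O) {
  mol <- bundle$molecule
  shells <- bundle$shells
  ao <- eval_ao(shells, mol, points)
  n <- nrow(points)
  nao <- n_ao(shells)
  centers <- mol$coords[ao$ao$center, , drop = FALSE]
  # complex density matrix to first order in B
  Dt <- bundle$density + 1i * (B[1] * bundle$perturbed_density[[1]] +
                               B[2] * bundle$perturbed_density[[2]] +
                               B[3] * bundle$perturbed_density[[3]])
  # GIAO phases: chi~_mu = exp(-i/2 (B x (R_mu - R_O)) . r) chi_mu
  J <- matrix(0, n, 3)
  phase_vec <- t(apply(centers, 1, function(Rm) {
    d <- Rm - R_O
    0.5 * c(B[2] * d[3] - B[3] * d[2], B[3] * d[1] - B[1] * d[3],
            B[1] * d[2] - B[2] * d[1])   # (1/2) B x (R_mu - R_O)
  }))
  # phi_mu(r) = -(phase_vec_mu . r); chi~ = exp(i phi) chi
  G <- list(ao$dx, ao$dy, ao$dz)
  for (p in seq_len(n)) {
    r <- points[p, ]
    phi <- -(phase_vec %*% r)[, 1]
    ph <- exp(1i * phi)
    chi_t <- ph * ao$values[p, ]
    A <- 0.5 * c(B[2] * (r[3] - R_O[3]) - B[3] * (r[2] - R_O[2]),
                 B[3] * (r[1] - R_O[1]) - B[1] * (r[3] - R_O[3]),
                 B[1] * (r[2] - R_O[2]) - B[2] * (r[1] - R_O[1]))
    for (al in 1:3) {
      grad_t <- ph * (1i * (-phase_vec[, al]) * ao$values[p, ] + G[[al]][p, ])
      op_ket <- -1i * grad_t + A[al] * chi_t
      J[p, al] <- -Re(sum(Dt * outer(Conj(chi_t), op_ket)))
    }
  }
  J
}

# finite-field CDT tensor, 4th-order central differences, arbitrary origin
oracle_cdt <- function(bundle, points, h = 2e-3, R_O = c(0.3, -0.7, 0.5)) {
  points <- matrix(as.numeric(points), ncol = 3)
  Tn <- array(0, c(nrow(points), 3, 3))
  for (b in 1:3) {
    e <- c(0, 0, 0); e[b] <- 1
    J1p <- .oracle_current_finite(bundle, points, h * e, R_O)
    J1m <- .oracle_current_finite(bundle, points, -h * e, R_O)
    J2p <- .oracle_current_finite(bundle, points, 2 * h * e, R_O)
    J2m <- .oracle_current_finite(bundle, points, -2 * h * e, R_O)
    Tn[, , b] <- (8 * (J1p - J1m) - (J2p - J2m)) / (12 * h)
  }
  Tn
}

# analytic on-axis field of an ideal current loop (radius R, current I),
# a.u. Biot-Savart prefactor alpha^2: B(z) = 2 pi alpha^2 I R^2 / (R^2+z^2)^(3/2)
oracle_loop_axis_field <- function(R, I, z) {
  2 * pi * shieldens_constants$alpha2 * I * R^2 / (R^2 + z^2)^1.5
}

# sigma_zz of a Gaussian-profile loop (radius R, width w, strength kappa,
# diatropic) for a nucleus at the loop center, by 2-d quadrature of the
# closed-form integrand in the (s, z) half-plane (independent of the
# package's grids).
oracle_loop_center_sigma_zz <- function(R, w, kappa) {
  norm2d <- 1 / (2 * pi * w^2)
  f <- function(s, z) {
    prof <- norm2d * exp(-((s - R)^2 + z^2) / (2 * w^2))
    kappa * prof * s^2 / (s^2 + z^2)^1.5
  }
  inner <- function(z) {
    vapply(z, function(zz) {
      stats::integrate(function(s) f(s, zz), 0, R + 12 * w,
                       rel.tol = 1e-11, abs.tol = 1e-14,
                       subdivisions = 500L)$value
    }, numeric(1))
  }
  # integrand is even in z; the inner integral diverges logarithmically at
  # z = 0 exactly (integrable in z), so keep z = 0 off the outer nodes
  v <- 2 * stats::integrate(inner, 0, 12 * w, rel.tol = 1e-10,
                            subdivisions = 500L)$value
  2 * pi * shieldens_constants$alpha2 * v * 1e6  # ppm
}

# Lamb shielding of a normalized Gaussian density rho ~ exp(-a r^2) (ppm)
oracle_lamb_gaussian <- function(a, n_electrons = 1) {
  shieldens_constants$alpha2 / 3 * n_electrons * 2 * sqrt(a / pi) * 1e6
}

# rigid translation of a bundle by t. The GIAO phase factors depend on the
# absolute shell centers, so the engine solution for the translated geometry
# carries center-pair phases; to first order in B the perturbed matrices
# transform as
#   P'[mu, nu] = P[mu, nu] + 1/2 [(R_nu - R_mu) x t]_beta D[mu, nu].
translate_bundle <- function(b, t0) {
  R <- b$molecule$coords
  P2 <- lapply(1:3, function(be) {
    P <- b$perturbed_density[[be]]
    m <- nrow(P)
    for (mu in seq_len(m)) for (nu in seq_len(m)) {
      dR <- R[nu, ] - R[mu, ]
      cr <- c(dR[2] * t0[3] - dR[3] * t0[2],
              dR[3] * t0[1] - dR[1] * t0[3],
              dR[1] * t0[2] - dR[2] * t0[1])
      P[mu, nu] <- P[mu, nu] + 0.5 * cr[be] * b$density[mu, nu]
    }
    P
  })
  response_bundle(molecule(b$molecule$element,
                           sweep(b$molecule$coords, 2, -t0)),
                  b$shells, b$overlap, b$density, P2, b$n_electrons)
}

# random valid minimal bundle on m s-type centers (for property tests)
random_min_bundle <- function(m = 2, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::runif(3 * m, -1.5, 1.5), m, 3)
  expo <- stats::runif(m, 0.6, 2.5)
  Draw <- matrix(stats::rnorm(m * m), m, m)
  D <- (Draw + t(Draw)) / 2
  P <- lapply(1:3, function(i) {
    A <- matrix(stats::rnorm(m * m, sd = 0.3), m, m)
    A - t(A)
  })
  make_min_bundle(centers, expo, D, P)
}
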