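test_that("thin loops reproduce the textbook center and on-axis fields", {
  # sigma_zz at the loop center equals the on-axis induced-field magnitude
  # divided by the unit field: thin-profile limit mu0 I / (2R) in a.u.
  R0 <- 3; k <- 1; w <- 0.02
  lp <- make_loop_provider(loop_model(radius = R0, strength = k, width = w))
  mol <- molecule("He", matrix(0, 1, 3))
  # integrate numerically over a narrow torus around the loop
  sref <- oracle_loop_center_sigma_zz(R0, w, k)
  thin <- 2 * pi * shieldens_constants$alpha2 * k / R0 * 1e6
  expect_equal(sref, thin, tolerance = 1e-4)  # w << R limit
  # on-axis formula at finite height, via the same 2-d profile integral
  z0 <- 2
  f <- function(s, z) {
    prof <- exp(-((s - R0)^2 + z^2) / (2 * w^2)) / (2 * pi * w^2)
    k * prof * s^2 / (s^2 + (z - z0)^2)^1.5
  }
  inner <- function(z) vapply(z, function(zz)
    stats::integrate(function(s) f(s, zz), 0, R0 + 10 * w,
                     rel.tol = 1e-10)$value, numeric(1))
  v <- stats::integrate(inner, -10 * w, 10 * w, rel.tol = 1e-9)$value
  s_axis <- 2 * pi * shieldens_constants$alpha2 * v * 1e6
  axis_ref <- oracle_loop_axis_field(R0, k, z0) * 1e6
  expect_equal(s_axis, axis_ref, tolerance = 1e-4)
})

test_that("swapping tropicity negates the provider everywhere", {
  m1 <- loop_model(radius = 2, strength = 1.3, width = 0.5,
                   tropicity = "diatropic")
  m2 <- loop_model(radius = 2, strength = 1.3, width = 0.5,
                   tropicity = "paratropic")
  p1 <- make_loop_provider(m1); p2 <- make_loop_provider(m2)
  set.seed(5)
  pts <- matrix(stats::runif(60, -3, 3), 20, 3)
  for (b in 1:3) expect_equal(p1(pts, b), -p2(pts, b), tolerance = 1e-15)
})

test_that("provider output scales linearly with circulation strength", {
  set.seed(6)
  pts <- matrix(stats::runif(30, -3, 3), 10, 3)
  p1 <- make_loop_provider(loop_model(radius = 2.2, strength = 1, width = 0.6))
  p3 <- make_loop_provider(loop_model(radius = 2.2, strength = 3, width = 0.6))
  expect_equal(3 * p1(pts, 3), p3(pts, 3), tolerance = 1e-14)
  mol <- molecule("He", matrix(0, 1, 3))
  grids <- build_grids(mol, radial_accuracy = 1e-8, angular_order = 110)
  r1 <- integrate_component(p1, mol, 1, "zz", grids)$total
  r3 <- integrate_component(p3, mol, 1, "zz", grids)$total
  expect_equal(r3, 3 * r1, tolerance = 1e-12)
})

test_that("the vortex shielding decays with nucleus displacement and rotates covariantly", {
  vx <- make_vortex_provider(vortex_model(exponent = 1.5))
  grids0 <- build_grids(molecule("He", matrix(0, 1, 3)),
                        radial_accuracy = 1e-10, angular_order = 110)
  near <- integrate_component(vx, molecule("He", matrix(c(0, 0, 3), 1)),
                              1, "isotropic", grids0)$total
  far <- integrate_component(vx, molecule("He", matrix(c(0, 0, 6), 1)),
                             1, "isotropic", grids0)$total
  expect_gt(abs(near), abs(far))
  expect_lt(abs(far), abs(oracle_lamb_gaussian(1.5)) / 50)

  # sigma_zz of an xy-plane vortex equals sigma_xx of the same vortex
  # rotated into the yz-plane: for the isotropic Gaussian vortex this is
  # the statement that the tensor is diagonal and symmetric under axis
  # relabeling
  mol <- molecule("He", matrix(0, 1, 3))
  rzz <- integrate_component(vx, mol, 1, "zz", grids0)$total
  rxx <- integrate_component(vx, mol, 1, "xx", grids0)$total
  expect_equal(rzz, rxx, tolerance = 1e-10)
})

test_that("analytic providers pass divergence checks under refinement", {
  providers <- list(
    make_loop_provider(loop_model(radius = 2.5, strength = 1, width = 0.7)),
    make_vortex_provider(vortex_model(exponent = 2)),
    benzene_like_composite()$provider)
  pt <- c(1.1, -0.6, 0.4)
  for (p in providers) {
    r_coarse <- max(abs(divergence_residual(p, pt, h = 2e-3)))
    r_fine <- max(abs(divergence_residual(p, pt, h = 5e-4)))
    expect_lt(r_fine, 1e-5)
    expect_lte(r_fine, r_coarse + 1e-12)
  }
})

test_that("minimal bundles reject invariant violations and zero matrices give zero", {
  expect_error(make_min_bundle(rbind(c(0, 0, 0), c(0, 0, 1)), c(1, 1),
                               matrix(c(1, 0.2, 0.3, 1), 2, 2)),
               "not symmetric")
  asym <- matrix(c(0, 0.1, 0.1, 0), 2, 2)  # symmetric, not antisymmetric
  expect_error(make_min_bundle(rbind(c(0, 0, 0), c(0, 0, 1)), c(1, 1),
                               diag(2), perturbed = replicate(3, asym,
                                                              simplify = FALSE)),
               "antisymmetric")
  b0 <- make_min_bundle(matrix(0, 1, 3), 1.1, matrix(0, 1, 1))
  expect_equal(max(abs(eval_cdt(b0, matrix(stats::rnorm(9), 3, 3))$tensor)), 0)
})

test_that("the composite model reproduces the expected map topology", {
  bz <- benzene_like_composite()
  molH <- molecule(c(bz$molecule$element, "H"),
                   rbind(bz$molecule$coords, c(4.69, 0, 0)))
  dens <- function(pts, off = 0) {
    shielding_density(bz$provider, molH, 7, "zz", cbind(pts, off))$values
  }
  # 1 a0 above the plane: positive band outside the perimeter loop
  outside <- rbind(c(5.0, 0), c(0, 5.0), c(-5.0, 0), c(0, -5.0))
  expect_true(all(dens(outside, off = 1) > 0))
  # removing the paratropic inner loop removes the far-side negative
  # inner region
  x_far_inner <- rbind(c(-1.2, 0))
  expect_lt(dens(x_far_inner)[1], 0)
  bz2 <- benzene_like_composite(include_inner = FALSE)
  dens2 <- function(pts, off = 0) {
    shielding_density(bz2$provider, molH, 7, "zz", cbind(pts, off))$values
  }
  expect_gte(dens2(x_far_inner)[1], 0)
  # the map is 6-fold symmetric when measured from the ring center
  molc <- molecule(c(bz$molecule$element, "H"),
                   rbind(bz$molecule$coords, c(0, 0, 0.1)))
  probe <- function(th) {
    p <- cbind(3.2 * cos(th), 3.2 * sin(th), 1)
    shielding_density(bz$provider, molc, 7, "zz", p)$values
  }
  th0 <- 0.37
  vals <- vapply(th0 + 2 * pi * (0:5) / 6, probe, numeric(1))
  expect_lt(max(abs(vals - vals[1])), 1e-10 * max(1, abs(vals[1])))
})
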