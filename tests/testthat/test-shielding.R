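test_that("the Biot-Savart kernel has the cross-product structure", {
  R_I <- c(0, 0, 0)
  K <- biot_savart_kernel(c(0, 0, 2), R_I)   # u along +z
  # J along x must contribute only to the y density row: (x-hat x z-hat) = -y-hat
  contrib <- K %*% c(1, 0, 0)
  expect_equal(contrib[1], 0); expect_equal(contrib[3], 0)
  expect_lt(contrib[2], 0)

  # norm scales as |u|^-2
  n1 <- norm(biot_savart_kernel(c(0, 0, 1), R_I), "F")
  n4 <- norm(biot_savart_kernel(c(0, 0, 4), R_I), "F")
  expect_equal(n1 / n4, 16, tolerance = 1e-12)

  # exclusion sentinel
  K0 <- biot_savart_kernel(c(0, 0, 1e-12), R_I)
  expect_true(attr(K0, "excluded"))
  expect_equal(max(abs(K0)), 0)
})

test_that("a discretized unit current loop assembles the textbook center field", {
  # unit loop radius R in the xy-plane, nucleus at the center; summing
  # K %*% J dl over segments gives magnitude mu0 I / (2R) = 2 pi alpha^2 I / R
  R <- 2.5; I <- 1; N <- 1e4
  th <- 2 * pi * (seq_len(N) - 0.5) / N
  dl <- 2 * pi * R / N
  pts <- cbind(R * cos(th), R * sin(th), 0)
  Jdir <- cbind(-sin(th), cos(th), 0)
  acc <- c(0, 0, 0)
  for (k in seq_len(N)) {
    K <- biot_savart_kernel(pts[k, ], c(0, 0, 0))
    acc <- acc + K %*% (I * Jdir[k, ]) * dl
  }
  expect_equal(sqrt(sum(acc^2)),
               2 * pi * shieldens_constants$alpha2 * I / R,
               tolerance = 1e-8)
  # +phi circulation reinforces the field at the center (deshields):
  # negative sigma contribution; a diatropic current circulates along -phi
  expect_lt(acc[3], 0)
})

test_that("ring-current sign rules follow the current direction at the nucleus", {
  lp <- make_loop_provider(loop_model(radius = 3, strength = 1, width = 0.3))
  molc <- molecule("He", matrix(0, 1, 3))
  th <- 2 * pi * (0:7) / 8
  ring_pts <- cbind(3 * cos(th), 3 * sin(th), 0)
  # diatropic ring, nucleus at the center: positive along the whole ring
  f <- shielding_density(lp, molc, 1, "zz", ring_pts)
  expect_true(all(f$values > 0))
  # nucleus outside the ring: positive on the far arc, negative on the near arc
  molo <- molecule("He", matrix(c(5, 0, 0), 1))
  fo <- shielding_density(lp, molo, 1, "zz", ring_pts)
  far <- which(ring_pts[, 1] < -2); near <- which(ring_pts[, 1] > 2)
  expect_true(all(fo$values[far] > 0))
  expect_true(all(fo$values[near] < 0))
  # zero provider
  z <- current_provider(function(points, beta) 0 * points)
  fz <- shielding_density(z, molc, 1, "zz", ring_pts)
  expect_equal(max(abs(fz$values)), 0)
})

test_that("loop shielding integral matches the analytic profile integral", {
  R0 <- 3; w <- 0.8; k <- 1
  lp <- make_loop_provider(loop_model(radius = R0, strength = k, width = w))
  mol <- molecule("He", matrix(0, 1, 3))
  grids <- build_grids(mol, radial_accuracy = 1e-12, angular_order = 194)
  res <- integrate_component(lp, mol, 1, "zz", grids)
  ref <- oracle_loop_center_sigma_zz(R0, w, k)
  expect_equal(res$total, ref, tolerance = 1e-6)
  expect_equal(res$total, res$positive + res$negative, tolerance = 1e-12)
})

test_that("a Gaussian Larmor current reproduces the Lamb shielding", {
  a <- 2
  vx <- make_vortex_provider(vortex_model(exponent = a, n_electrons = 1))
  mol <- molecule("He", matrix(0, 1, 3))
  grids <- build_grids(mol, radial_accuracy = 1e-12, angular_order = 110)
  res <- integrate_component(vx, mol, 1, "isotropic", grids)
  expect_equal(res$total, oracle_lamb_gaussian(a), tolerance = 0.01 / 28)
})

test_that("atomic decomposition is additive and percentages close to 100", {
  bz <- benzene_like_composite()
  molH <- molecule(c(bz$molecule$element, "H"),
                   rbind(bz$molecule$coords, c(4.69, 0, 0)))
  grids <- build_grids(molH, radial_accuracy = 1e-8, angular_order = 110)
  tab <- decompose_atomic(bz$provider, molH, 7, grids, component = "zz")
  glob <- integrate_component(bz$provider, molH, 7, "zz", grids)
  i_tot <- which(tab$domain == "total")
  # same points, same weights: row sums equal the global integral exactly
  expect_equal(tab$total[i_tot], glob$total, tolerance = 1e-10)
  expect_equal(sum(tab$total[-i_tot]), tab$total[i_tot], tolerance = 1e-8)
  expect_equal(sum(tab$percentage[-i_tot]), 100, tolerance = 1e-6)
  expect_equal(tab$positive[i_tot] + tab$negative[i_tot], tab$total[i_tot],
               tolerance = 1e-8)
  # per-row split closes exactly
  expect_equal(tab$positive + tab$negative, tab$total, tolerance = 1e-8)
})

test_that("labeling maps merge symmetry-equivalent rows", {
  bz <- benzene_like_composite()
  mol <- bz$molecule
  grids <- build_grids(mol, radial_accuracy = 1e-8, angular_order = 50)
  lab <- list(ipso = 1L, ortho = c(2L, 6L), meta = c(3L, 5L), para = 4L)
  tab <- decompose_atomic(bz$provider, mol, 1, grids, component = "zz",
                          labeling = lab)
  expect_equal(tab$domain, c("ipso", "ortho", "meta", "para", "total"))
  full <- decompose_atomic(bz$provider, mol, 1, grids, component = "zz")
  expect_equal(tab$total[tab$domain == "ortho"],
               sum(full$total[full$domain %in% c("C2", "C6")]),
               tolerance = 1e-12)
  expect_error(decompose_atomic(bz$provider, mol, 1, grids,
                                labeling = list(all = 1:7)),
               "absent atom")
})

test_that("reversing the circulation flips every density and table entry", {
  di <- make_loop_provider(loop_model(radius = 2.5, strength = 1, width = 0.6,
                                      tropicity = "diatropic"))
  pa <- make_loop_provider(loop_model(radius = 2.5, strength = 1, width = 0.6,
                                      tropicity = "paratropic"))
  mol <- molecule("He", matrix(c(1.2, 0.4, 0.2), 1))
  set.seed(31)
  pts <- matrix(stats::runif(60, -3, 3), 20, 3)
  f1 <- shielding_density(di, mol, 1, "zz", pts)
  f2 <- shielding_density(pa, mol, 1, "zz", pts)
  expect_equal(f1$values, -f2$values, tolerance = 1e-14)
  grids <- build_grids(mol, radial_accuracy = 1e-8, angular_order = 110)
  r1 <- integrate_component(di, mol, 1, "zz", grids)
  r2 <- integrate_component(pa, mol, 1, "zz", grids)
  expect_equal(r1$total, -r2$total, tolerance = 1e-12)
  expect_equal(r1$positive, -r2$negative, tolerance = 1e-12)
})

test_that("isotropic averaging is the arithmetic mean and is linear", {
  expect_equal(isotropic(3, 3, 3), 3)
  expect_equal(isotropic(1, 2, 3), 2)
  vx <- make_vortex_provider(vortex_model(exponent = 1.4))
  mol <- molecule("He", matrix(0, 1, 3))
  grids <- build_grids(mol, radial_accuracy = 1e-8, angular_order = 50)
  parts <- lapply(c("xx", "yy", "zz"), function(cp)
    integrate_component(vx, mol, 1, cp, grids)$total)
  iso <- integrate_component(vx, mol, 1, "isotropic", grids)$total
  expect_equal(isotropic(parts[[1]], parts[[2]], parts[[3]]), iso,
               tolerance = 1e-10)
})

test_that("integrated shieldings are invariant under rigid translation", {
  b <- random_min_bundle(2, seed = 15)
  t0 <- c(0.7, -1.1, 0.4)
  b2 <- translate_bundle(b, t0)
  g1 <- build_grids(b$molecule, radial_accuracy = 1e-8, angular_order = 110,
                    basis = b$shells)
  g2 <- build_grids(b2$molecule, radial_accuracy = 1e-8, angular_order = 110,
                    basis = b2$shells)
  r1 <- integrate_component(bundle_provider(b), b$molecule, 1, "isotropic", g1)
  r2 <- integrate_component(bundle_provider(b2), b2$molecule, 1, "isotropic", g2)
  expect_equal(r1$total, r2$total, tolerance = 1e-7)
})

test_that("a zero provider gives a degenerate all-zero table with a flag", {
  z <- current_provider(function(points, beta) 0 * points)
  mol <- molecule(c("C", "H"), rbind(c(0, 0, 0), c(0, 0, 2)))
  grids <- build_grids(mol, radial_accuracy = 1e-6, angular_order = 26)
  tab <- decompose_atomic(z, mol, 1, grids)
  expect_true(attr(tab, "degenerate"))
  expect_equal(max(abs(tab$total)), 0)
  expect_equal(max(abs(tab$percentage)), 0)
})
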