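test_that("the Becke cell function has the required shape", {
  expect_equal(becke_cell(0, 3), 0.5)
  expect_equal(becke_cell(1, 3), 0)
  expect_equal(becke_cell(-1, 3), 1)
  # triple-iterated polynomial oracle at mu = 0.5
  p <- 0.5
  for (i in 1:3) p <- 1.5 * p - 0.5 * p^3
  expect_equal(becke_cell(0.5, 3), (1 - p) / 2, tolerance = 1e-15)
  expect_equal(becke_cell(0.5, 3), 0.01235, tolerance = 1e-4)
  # monotone decreasing
  mu <- seq(-1, 1, length.out = 201)
  expect_true(all(diff(becke_cell(mu, 3)) <= 0))
  expect_error(becke_cell(1.001), "outside")
})

test_that("Becke weights are a partition of unity", {
  mol1 <- molecule("He", matrix(c(1, 2, 3), 1))
  expect_equal(becke_weights(c(9, -4, 0.3), mol1), 1)

  # midpoint of two identical atoms
  mol2 <- molecule(c("C", "C"), rbind(c(0, 0, -1), c(0, 0, 1)))
  expect_equal(becke_weights(c(0, 0, 0), mol2), c(0.5, 0.5))

  # random centers and points
  set.seed(42)
  mol5 <- molecule(sample(c("C", "H", "O", "N"), 5, replace = TRUE),
                   matrix(stats::runif(15, -3, 3), 5, 3))
  pts <- matrix(stats::runif(3000, -5, 5), 1000, 3)
  W <- becke_weights(pts, mol5)
  expect_true(all(W >= 0 & W <= 1))
  expect_lt(max(abs(rowSums(W) - 1)), 1e-12)
  # without size adjustment as well
  W2 <- becke_weights(pts, mol5, becke_spec(size_adjust = FALSE))
  expect_lt(max(abs(rowSums(W2) - 1)), 1e-12)
})

test_that("radial quadrature reproduces closed-form integrals", {
  g <- radial_grid(alpha_min = 0.1, alpha_max = 100, accuracy = 1e-10)
  expect_true(all(diff(g$r) > 0))
  expect_true(all(g$w > 0))
  expect_equal(sum(g$w * exp(-g$r^2)), sqrt(pi) / 4, tolerance = 1e-8)
  expect_equal(sum(g$w * exp(-2 * g$r)), 0.25, tolerance = 1e-8)
})

test_that("tightening the radial accuracy never increases the error", {
  errs <- vapply(c(1e-6, 1e-8, 1e-10, 1e-12), function(acc) {
    g <- radial_grid(alpha_min = 0.1, alpha_max = 100, accuracy = acc)
    abs(sum(g$w * exp(-g$r^2)) - sqrt(pi) / 4) +
      abs(sum(g$w * exp(-2 * g$r)) - 0.25)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-14))
  ns <- vapply(c(1e-6, 1e-10), function(acc)
    radial_grid(element = "C", accuracy = acc)$n, numeric(1))
  expect_gt(ns[2], ns[1])
  expect_error(radial_grid(element = "Xx"), "no default exponent range")
})

test_that("angular grids integrate monomials and harmonics to round-off", {
  for (ord in lebedev_orders()) {
    g <- lebedev_grid(ord)
    x <- g$points[, 1]; y <- g$points[, 2]; z <- g$points[, 3]
    expect_equal(sum(g$weights), 1, tolerance = 1e-13)
    expect_lt(max(abs(rowSums(g$points^2) - 1)), 1e-12)
    expect_equal(sum(g$weights * x^2), 1 / 3, tolerance = 1e-13)
    expect_lt(abs(sum(g$weights * x * y * z^2)), 1e-14)
    if (g$degree >= 4) {
      expect_equal(sum(g$weights * (x^4 + y^4 + z^4)), 3 / 5,
                   tolerance = 1e-13)
    }
    # every spherical harmonic up to the algebraic degree integrates to 0
    for (l in seq_len(min(g$degree, 6))) {
      for (P in solid_harmonics(l, "sphere")) {
        expect_lt(abs(sum(g$weights * .poly_eval(P, x, y, z))), 1e-12)
      }
    }
  }
  expect_error(lebedev_grid(75), "supported orders")
})

test_that("molecular grids integrate Gaussian densities over all space", {
  # one-atom grid: Becke factor 1, spherical Gaussian of unit charge
  mol1 <- molecule("He", matrix(c(0.3, -0.1, 0.2), 1))
  g1 <- build_grids(mol1, radial_accuracy = 1e-10, angular_order = 50)
  expect_length(g1, 1)
  a <- 0.9
  rho <- function(p) {
    d <- sweep(p, 2, mol1$coords[1, ])
    (a / pi)^1.5 * exp(-a * rowSums(d^2))
  }
  expect_equal(grid_integrate(g1, rho), 1, tolerance = 1e-8)

  # two-center density: domain decomposition must still integrate exactly
  mol2 <- molecule(c("C", "H"), rbind(c(0, 0, 0), c(0, 0, 2.05)))
  g2 <- build_grids(mol2, radial_accuracy = 1e-10, angular_order = 194)
  rho2 <- function(p) {
    d1 <- rowSums(sweep(p, 2, mol2$coords[1, ])^2)
    d2 <- rowSums(sweep(p, 2, mol2$coords[2, ])^2)
    2 * (1.2 / pi)^1.5 * exp(-1.2 * d1) + (0.5 / pi)^1.5 * exp(-0.5 * d2)
  }
  expect_equal(grid_integrate(g2, rho2), 3, tolerance = 1e-6)
  # per-domain contributions sum to the whole-space integral by construction
  parts <- vapply(g2, function(g) sum(g$weights * rho2(g$points)), numeric(1))
  expect_equal(sum(parts), grid_integrate(g2, rho2), tolerance = 1e-14)
})

test_that("electron counts integrate from bundle densities", {
  b <- random_min_bundle(2, seed = 12)
  grids <- build_grids(b$molecule, radial_accuracy = 1e-10,
                       angular_order = 194, basis = b$shells)
  rho <- function(p) {
    ao <- eval_ao(b$shells, b$molecule, p)
    rowSums((ao$values %*% b$density) * ao$values)
  }
  expect_equal(grid_integrate(grids, rho), b$n_electrons, tolerance = 1e-5)
})

test_that("production grids for an aromatic ring have reference-scale point counts", {
  # per-atom counts at production settings are expected on the order of
  # 2e4 per carbon and slightly fewer per hydrogen (unpruned grids)
  mol <- read_xyz(system.file("extdata", "benzene_ring_synthetic.xyz",
                              package = "shieldens"))
  grids <- build_grids(mol, radial_accuracy = 1e-12, angular_order = 194)
  counts <- vapply(grids, function(g) nrow(g$points), numeric(1))
  expect_true(all(counts[1:6] > 1e4 & counts[1:6] < 5e4))
  expect_true(all(counts[7:12] > 1e4 & counts[7:12] < 5e4))
  expect_lt(counts[7], counts[1])  # hydrogen grids are smaller than carbon
  expect_true(all(vapply(grids, function(g) all(g$weights >= 0), logical(1))))
})

test_that("grid text dumps round trip", {
  mol <- molecule(c("C", "H"), rbind(c(0, 0, 0), c(0, 0, 2)))
  grids <- build_grids(mol, radial_accuracy = 1e-6, angular_order = 26)
  f <- withr::local_tempfile(fileext = ".txt")
  write_grid(grids, f)
  back <- read_grid(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$points, grids[[1]]$points)
  expect_equal(back[[2]]$weights, grids[[2]]$weights)
})
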