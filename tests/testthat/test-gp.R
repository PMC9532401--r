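# Reduced-rank manifold GP machinery.

test_that("spectral densities are positive, decreasing, correctly normalized", {
  om <- seq(0, 5, by = 0.25)
  for (fam in c("rbf", "matern52")) {
    S <- spectral_density(kernel_spec(fam, rho = 1.3), om)
    expect_true(all(S > 0))
    expect_true(all(diff(S) < 0))
  }
  # rbf closed form against a numerical 2-D Fourier transform (Hankel)
  rho <- 0.8
  for (w in c(0.5, 1 / rho, 2)) {
    oracle <- 2 * pi * stats::integrate(function(r) {
      exp(-r^2 / (2 * rho^2)) * besselJ(w * r, 0) * r
    }, 0, Inf)$value
    expect_equal(spectral_density(kernel_spec("rbf", rho = rho), w), oracle,
                 tolerance = 1e-6)
  }
  # Matern-5/2 has the heavier tail: ratio diverges at high frequency
  r1 <- spectral_density(kernel_spec("matern52", rho = 1), 8) /
    spectral_density(kernel_spec("rbf", rho = 1), 8)
  r0 <- spectral_density(kernel_spec("matern52", rho = 1), 1) /
    spectral_density(kernel_spec("rbf", rho = 1), 1)
  expect_gt(r1, 1e3 * r0)
  expect_error(spectral_density(list(family = "boxcar", rho = 1), 1),
               "unknown")
})

test_that("spectral weights are non-increasing across the spectrum", {
  b <- fx_coarse_basis()
  for (fam in c("rbf", "matern52")) {
    w <- erpfield:::spectral_weights(sub_basis_for_test(b, 100),
                                     kernel_spec(fam, rho = 8))
    expect_true(all(diff(w) <= 1e-12))
  }
})

test_that("field evaluation is affine in eta with mean m", {
  b <- fx_coarse_basis()
  bs <- sub_basis_for_test(b, 30)
  kr <- kernel_spec("rbf", rho = 8, alpha = 2)
  expect_equal(evaluate_field(bs, kr, 7, rep(0, 30)),
               rep(7, nrow(fx_coarse()$vertices)))
  ea <- stats::rnorm(30); eb <- stats::rnorm(30)
  fa <- evaluate_field(bs, kr, 7, ea)
  fb <- evaluate_field(bs, kr, 7, eb)
  fab <- evaluate_field(bs, kr, 7, ea + eb)
  expect_equal(fab, fa + fb - 7, tolerance = 1e-10)
  expect_error(evaluate_field(bs, kr, 0, rep(0, 29)), "length")
})

test_that("sampling is seeded, centered, and has pointwise sd near alpha", {
  b <- fx_coarse_basis()
  kr <- kernel_spec("matern52", rho = 6, alpha = 3)
  f1 <- sample_field(b, kr, 10, seed = 42)
  f2 <- sample_field(b, kr, 10, seed = 42)
  expect_identical(f1, f2)
  draws <- vapply(1:2000, function(s) sample_field(b, kr, 10, seed = s),
                  numeric(b$n_vertices))
  expect_lt(max(abs(rowMeans(draws) - 10)), 1)
  sds <- apply(draws, 1, stats::sd)
  expect_lt(max(abs(sds - kr$alpha)) / kr$alpha, 0.1)
})

test_that("nearby vertices are more correlated than distant ones", {
  b <- fx_coarse_basis()
  m <- fx_coarse()
  kr <- kernel_spec("rbf", rho = 6, alpha = 1)
  draws <- vapply(1:400, function(s) sample_field(b, kr, 0, seed = s),
                  numeric(b$n_vertices))
  gd <- mesh_geodesics(m, from = 1)
  near <- which(gd > 0 & gd < 5)[1]
  far <- which.max(gd)
  expect_gt(stats::cor(draws[1, ], draws[near, ]),
            stats::cor(draws[1, ], draws[far, ]) + 0.3)
})

test_that("a small basis for a rough kernel triggers the resolution warning", {
  b <- fx_coarse_basis()
  expect_warning(sample_field(sub_basis_for_test(b, 6),
                              kernel_spec("rbf", rho = 1), 0, 1),
                 "eigenpairs")
})

test_that("lengthscale calibration recovers coordinate units on flat geometry", {
  sq <- fx_square_mesh(n = 29, scale = 10) # 10 x 10 units
  b <- solve_eigenproblem(sq, 200)
  kr <- kernel_spec("rbf", rho = 1.5)
  s <- calibrate_lengthscale_mm(sq, b, kr, n_samples = 800, seed = 3)
  expect_lt(abs(s - 1), 0.1)
  # seed consistency at moderate sample counts
  s2 <- calibrate_lengthscale_mm(sq, b, kr, n_samples = 800, seed = 9)
  expect_lt(abs(s - s2) / s, 0.05)
})

test_that("lengthscale calibration follows the eigenvalue scaling law", {
  m <- fx_coarse()
  b <- solve_eigenproblem(m, 150)
  kr <- kernel_spec("rbf", rho = 4)
  s1 <- calibrate_lengthscale_mm(m, b, kr, n_samples = 500, seed = 5)
  ms <- tri_mesh(m$vertices * 2, m$faces)
  bs <- solve_eigenproblem(ms, 150)
  s2 <- calibrate_lengthscale_mm(ms, bs, kernel_spec("rbf", rho = 8),
                                 n_samples = 500, seed = 5)
  # lambda scales 1/4, rho doubled: identical spectral weights, so the
  # fitted mm-per-unit factor is unchanged
  expect_lt(abs(s1 - s2) / s1, 0.05)
  expect_error(
    calibrate_lengthscale_mm(m, b, kernel_spec("rbf", rho = 500),
                             n_samples = 100, seed = 1),
    "smaller rho")
})

test_that("field transfer between meshes is exact where it should be", {
  coarse <- fx_coarse()
  fine <- fx_sphere()
  const <- rep(3.5, nrow(coarse$vertices))
  expect_equal(transfer_field(const, coarse, fine),
               rep(3.5, nrow(fine$vertices)))
  # linear coordinate field on a flat mesh: small interpolation error
  sqc <- fx_square_mesh(n = 11, scale = 1)
  sqf <- fx_square_mesh(n = 21, scale = 1)
  lin <- sqc$vertices[, 1]
  tr <- transfer_field(lin, sqc, sqf, radius = 0.2)
  expect_lt(max(abs(tr - sqf$vertices[, 1])), 0.2)
  # coincident-vertex subset preserved exactly
  tr_self <- transfer_field(lin, sqc, sqc)
  expect_identical(tr_self, lin)
})
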