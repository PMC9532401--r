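# Meshes, Laplace-Beltrami operators, and the eigenbasis.

test_that("fixture meshes have the expected topology and area", {
  s <- make_fixture_mesh("sphere", radius = 2, subdivisions = 3)
  expect_length(s$boundary_vertices, 0)
  expect_lt(abs(mesh_area(s) - 4 * pi * 4) / (4 * pi * 4), 0.01)
  e <- make_fixture_mesh("ellipsoid-with-holes", radius = 1)
  expect_gt(length(e$boundary_vertices), 0)
  cyl <- make_fixture_mesh("cylinder-with-holes", radius = 1)
  expect_gt(length(cyl$boundary_vertices), 0)
  # deterministic construction
  s2 <- make_fixture_mesh("sphere", radius = 2, subdivisions = 3)
  expect_identical(s, s2)
})

test_that("invalid meshes are rejected with a reason", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  f_bad <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)) # edge 1-2 shared 3x
  expect_error(tri_mesh(v, f_bad), "non-manifold")
  v_col <- rbind(v, c(2, 0, 0)) # vertex 6 collinear with 1 and 2
  f_deg <- rbind(c(1, 2, 3), c(2, 1, 6))
  expect_error(tri_mesh(v_col, f_deg), "degenerate")
})

test_that("mesh OBJ and VTK round trips preserve geometry", {
  m <- make_fixture_mesh("sphere", subdivisions = 1)
  for (ext in c("obj", "vtk")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-7,
                 ignore_attr = TRUE)
    expect_equal(m2$faces, m$faces)
  }
})

test_that("operators: zero row sums, mass equals area, PSD stiffness", {
  m <- fx_coarse()
  ops <- build_lb_operator(m)
  expect_lt(max(abs(Matrix::rowSums(ops$stiffness))), 1e-10)
  expect_lt(abs(sum(Matrix::diag(ops$mass)) - mesh_area(m)) / mesh_area(m),
            1e-10)
  expect_true(Matrix::isSymmetric(ops$stiffness))
})

test_that("unit square Neumann spectrum: smallest nonzero eigenvalue is pi^2", {
  sq <- fx_square_mesh(n = 25)
  b <- solve_eigenproblem(sq, 4)
  expect_lt(b$values[1], 1e-8 * b$values[2])
  expect_lt(abs(b$values[2] - pi^2) / pi^2, 0.02)
  expect_lt(abs(b$values[3] - pi^2) / pi^2, 0.02)
})

test_that("eigenbasis is mass-orthonormal with a constant first mode", {
  b <- fx_coarse_basis()
  K <- 40
  phi <- b$vectors[, 1:K]
  G <- crossprod(phi, b$mass * phi)
  expect_lt(max(abs(G - diag(K))), 1e-8)
  expect_lt(b$values[1], 1e-8 * b$values[2])
  expect_lt(diff(range(b$vectors[, 1])), 1e-8)
  expect_equal(b$vectors[1, 1], 1 / sqrt(b$area), tolerance = 1e-8)
  expect_true(all(diff(b$values) >= -1e-10))
})

test_that("eigenvalues are isometry- and scale-covariant", {
  m <- make_fixture_mesh("sphere", radius = 1, subdivisions = 2)
  b <- solve_eigenproblem(m, 12)
  # rigid rotation: eigenvalues invariant
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mr <- tri_mesh(m$vertices %*% t(R), m$faces)
  br <- solve_eigenproblem(mr, 12)
  expect_equal(br$values, b$values, tolerance = 1e-6)
  # uniform rescale by s: eigenvalues scale as 1/s^2
  ms <- tri_mesh(m$vertices * 3, m$faces)
  bs <- solve_eigenproblem(ms, 12)
  expect_equal(bs$values, b$values / 9, tolerance = 1e-8)
})

test_that("solver input validation", {
  m <- fx_coarse()
  expect_error(solve_eigenproblem(m, 0), "between")
  expect_error(solve_eigenproblem(m, nrow(m$vertices) + 1), "between")
})

test_that("biharmonic distance is a distance and tracks geodesics", {
  b <- fx_coarse_basis()
  expect_equal(biharmonic_distance(b, 5, 5), 0)
  expect_equal(biharmonic_distance(b, 5, 37), biharmonic_distance(b, 37, 5))
  expect_error(biharmonic_distance(b, 0, 5), "out of range")
  # along a sphere, biharmonic distance increases with great-circle
  # separation (strong rank agreement)
  m <- fx_coarse()
  from <- 1
  gc <- acos(pmin(1, pmax(-1, (m$vertices %*% m$vertices[from, ]) /
                            (12.5^2))))
  others <- seq(2, nrow(m$vertices), by = 2)
  dbh <- biharmonic_distance(b, from, others)
  expect_gt(stats::cor(gc[others], dbh, method = "spearman"), 0.99)
})

test_that("eigenbasis cache round-trips and is keyed by mesh and K", {
  m <- fx_coarse()
  b <- sub_basis_for_test(fx_coarse_basis(), 20)
  dir <- withr::local_tempdir()
  cache_eigenbasis(b, m, dir)
  back <- load_eigenbasis(m, 20, dir)
  expect_equal(back$values, b$values, tolerance = 1e-8)
  expect_equal(back$vectors, b$vectors, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_null(load_eigenbasis(m, 21, dir)) # different K, different key
  expect_null(load_eigenbasis(tri_mesh(m$vertices * 1.01, m$faces), 20, dir))
})
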