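# Cotangent finite-element discretization of the Laplace-Beltrami
# operator on a triangle mesh, and the generalized eigenproblem
# S phi = lambda M phi that supplies the basis for reduced-rank Gaussian
# processes on the manifold.

#' Build the Laplace-Beltrami operators of a mesh
#'
#' Assembles the cotangent-weight stiffness matrix and the (lumped,
#' barycentric) mass matrix.  Natural (Neumann) boundary conditions are
#' implied: nothing special is done at boundary edges, so the constant
#' vector spans the stiffness null space on a connected mesh.
#'
#' @param mesh A `tri_mesh`.
#' @param lumped Use the lumped (diagonal) mass matrix (default TRUE);
#'   `FALSE` assembles the consistent linear FEM mass matrix.
#' @return List with sparse `stiffness` (1/mm^0, PSD) and `mass`
#'   (mm^2, SPD) matrices.
#' @export
build_lb_operator <- function(mesh, lumped = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(v)
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  e23 <- v[i3, , drop = FALSE] - v[i2, , drop = FALSE]
  e31 <- v[i1, , drop = FALSE] - v[i3, , drop = FALSE]
  e12 <- v[i2, , drop = FALSE] - v[i1, , drop = FALSE]
  area <- triangle_areas(v, f)
  # cot(angle at vertex k) = -dot(e_ki, e_kj) / (2 * area) with edge
  # vectors oriented away from k; standard half-cotangent weights.
  # angle at vertex 1 is between edges (v2 - v1) = e12 and (v3 - v1) = -e31
  cot1 <- rowSums(e12 * (-e31)) / (2 * area)
  cot2 <- rowSums((-e12) * e23) / (2 * area)
  cot3 <- rowSums((-e23) * e31) / (2 * area)
  # off-diagonal contributions: edge opposite vertex k gets -cot_k / 2
  ii <- c(i2, i3, i1, i3, i1, i2)
  jj <- c(i3, i2, i3, i1, i2, i1)
  xx <- -0.5 * c(cot1, cot1, cot2, cot2, cot3, cot3)
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::diag(S) <- 0
  Matrix::diag(S) <- -Matrix::rowSums(S)
  S <- methods::as(Matrix::forceSymmetric(S), "CsparseMatrix")
  if (lumped) {
    mdiag <- numeric(n)
    for (k in 1:3) {
      t <- tapply(rep(area / 3, 1), f[, k], sum)
      mdiag[as.integer(names(t))] <- mdiag[as.integer(names(t))] + t
    }
    M <- Matrix::Diagonal(n, mdiag)
  } else {
    ii <- c(i1, i2, i3, i1, i2, i1, i3, i2, i3)
    jj <- c(i1, i2, i3, i2, i1, i3, i1, i3, i2)
    xx <- c(rep(area / 6, 3), rep(area / 12, 6))
    M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  }
  list(stiffness = S, mass = M)
}

#' Solve the Laplace-Beltrami eigenproblem
#'
#' Computes the `K` smallest generalized eigenpairs of
#' `S phi = lambda M phi`, mass-orthonormalized (`t(Phi) M Phi = I`).
#' With the lumped mass matrix the problem reduces to a dense symmetric
#' standard eigenproblem on `M^-1/2 S M^-1/2`; the full spectrum is
#' computed (exact to solver precision, deterministic), which is
#' practical for meshes up to a few thousand vertices.
#'
#' @param mesh A `tri_mesh`, or a list as returned by
#'   [build_lb_operator()].
#' @param K Number of eigenpairs (1 <= K <= n).
#' @return Object of class `lb_basis`: `values` (ascending, 1/mm^2),
#'   `vectors` (n x K, mass-orthonormal), `mass` (diagonal of the lumped
#'   mass matrix), `area` (total surface area), `n_vertices`.
#' @export
solve_eigenproblem <- function(mesh, K) {
  if (inherits(mesh, "tri_mesh")) {
    ops <- build_lb_operator(mesh)
  } else {
    ops <- mesh
  }
  n <- nrow(ops$stiffness)
  if (K < 1 || K > n) stop("K must be between 1 and the vertex count")
  md <- Matrix::diag(ops$mass)
  if (any(md <= 0)) stop("mass matrix not positive definite")
  s <- 1 / sqrt(md)
  A <- as.matrix(ops$stiffness)
  A <- A * tcrossprod(s) # M^-1/2 S M^-1/2
  A <- (A + t(A)) / 2
  eg <- eigen(A, symmetric = TRUE)
  if (any(!is.finite(eg$values))) stop("eigen-solver returned non-finite values")
  ord <- order(eg$values)
  idx <- ord[seq_len(K)]
  vals <- eg$values[idx]
  vals[vals < 0 & vals > -1e-8 * max(abs(eg$values))] <- 0
  vecs <- eg$vectors[, idx, drop = FALSE] * s
  # deterministic sign: largest-magnitude entry positive
  for (k in seq_len(K)) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(list(values = vals, vectors = vecs, mass = md,
                 area = sum(md), n_vertices = n),
            class = "lb_basis")
}

#' @export
print.lb_basis <- function(x, ...) {
  cat(sprintf("lb_basis: %d modes on %d vertices; lambda in [%.3g, %.3g]\n",
              length(x$values), x$n_vertices, min(x$values), max(x$values)))
  invisible(x)
}

#' Biharmonic distance between mesh vertices
#'
#' Spectral distance `d^2 = sum_k (phi_k(i) - phi_k(j))^2 / lambda_k^2`
#' over modes with positive eigenvalue, a cheap surrogate for geodesic
#' distance that respects mesh topology.
#'
#' @param basis An `lb_basis` with at least 2 modes.
#' @param i Vertex index (scalar).
#' @param j Vertex indices (vector allowed).
#' @return Distances from `i` to each `j`.
#' @export
biharmonic_distance <- function(basis, i, j) {
  n <- basis$n_vertices
  if (any(c(i, j) < 1) || any(c(i, j) > n)) stop("vertex index out of range")
  pos <- basis$values > 1e-8 * max(basis$values)
  if (!any(pos)) stop("basis needs modes with positive eigenvalue")
  phi <- basis$vectors[, pos, drop = FALSE]
  lam <- basis$values[pos]
  d2 <- colSums((t(phi[j, , drop = FALSE]) - phi[i, ])^2 / lam^2)
  sqrt(pmax(d2, 0))
}

#' Cache an eigenbasis to disk
#'
#' Writes the basis to a CSV container (eigenvalues, mass diagonal, and
#' eigenfunction matrix) under a name keyed by a hash of the mesh
#' geometry and `K`, so stale caches are never reused across meshes.
#'
#' @param basis An `lb_basis`.
#' @param mesh The `tri_mesh` it was computed from.
#' @param dir Cache directory (created if needed).
#' @return The cache file path, invisibly.
#' @export
cache_eigenbasis <- function(basis, mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  key <- mesh_cache_key(mesh, length(basis$values))
  path <- file.path(dir, paste0("eigenbasis-", key, ".csv"))
  header <- data.frame(lambda = basis$values)
  utils::write.csv(cbind(header, mass = NA, t(basis$vectors)), path,
                   row.names = FALSE)
  # mass diagonal stored as an extra column block on the first rows
  utils::write.csv(data.frame(mass = basis$mass),
                   sub("[.]csv$", "-mass.csv", path), row.names = FALSE)
  invisible(path)
}

#' Load a cached eigenbasis
#'
#' @param mesh The `tri_mesh` the cache was built for.
#' @param K Number of modes.
#' @param dir Cache directory.
#' @return The `lb_basis`, or `NULL` if no cache entry exists.
#' @export
load_eigenbasis <- function(mesh, K, dir) {
  key <- mesh_cache_key(mesh, K)
  path <- file.path(dir, paste0("eigenbasis-", key, ".csv"))
  if (!file.exists(path)) return(NULL)
  tb <- utils::read.csv(path)
  mass <- utils::read.csv(sub("[.]csv$", "-mass.csv", path))$mass
  structure(list(values = tb$lambda,
                 vectors = t(as.matrix(tb[, -(1:2), drop = FALSE])),
                 mass = mass, area = sum(mass), n_vertices = length(mass)),
            class = "lb_basis")
}

mesh_cache_key <- function(mesh, K) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(c(sprintf("%.10g", as.vector(mesh$vertices)),
               as.character(as.vector(mesh$faces)), as.character(K)), tf)
  substr(unname(tools::md5sum(tf)), 1, 12)
}
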