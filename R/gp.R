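# Reduced-rank Gaussian processes on a mesh manifold: stationary kernel
# spectral densities evaluated at sqrt(eigenvalue) frequencies, field
# evaluation/sampling in the Laplace-Beltrami eigenbasis, and empirical
# lengthscale-to-distance calibration.
#
# A field is theta(x) = m + (alpha / |Phi_1|) * sum_k eta_k w_k phi_k(x)
# with w_k = sqrt(S(sqrt(lambda_k), rho) / sum_j S(sqrt(lambda_j), rho)).
# The weight normalization makes the pointwise prior standard deviation
# approximately equal alpha (in field units) for any K and rho; since the
# amplitude is inferred, any fixed normalization of the spectral density
# is admissible, and this one keeps alpha interpretable.

#' Kernel specification for manifold Gaussian processes
#'
#' @param family `"rbf"` (exponentiated quadratic) or `"matern52"`.
#' @param rho Lengthscale in mesh distance units (> 0).
#' @param alpha Amplitude in field units (> 0); approximately the
#'   pointwise prior standard deviation.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("rbf", "matern52"), rho = 1, alpha = 1) {
  family <- match.arg(family)
  if (!is.finite(rho) || rho <= 0) stop("rho must be positive")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  structure(list(family = family, rho = rho, alpha = alpha, d = 2),
            class = "kernel_spec")
}

#' Stationary spectral density in two dimensions
#'
#' The spectral density of the chosen kernel family with intrinsic
#' dimension d = 2, evaluated at angular frequency `omega` (typically
#' `sqrt(lambda_k)`).  Conventions: the exponentiated-quadratic kernel
#' `exp(-r^2 / (2 rho^2))` has `S(w) = 2 pi rho^2 exp(-rho^2 w^2 / 2)`;
#' the Matern-5/2 density is proportional to
#' `(5 / rho^2 + w^2)^(-7/2)`, normalized so that the kernel has unit
#' variance under the `(2 pi)^-d` inverse-transform convention.
#'
#' @param kernel A [kernel_spec()] (or family string).
#' @param omega Frequency argument (1/mm), `sqrt(lambda)`.
#' @param rho Lengthscale override (used when `kernel` is a string).
#' @return Strictly positive weights, decreasing in `omega`.
#' @export
spectral_density <- function(kernel, omega, rho = NULL) {
  if (is.character(kernel)) kernel <- kernel_spec(kernel, rho = rho)
  rho <- if (is.null(rho)) kernel$rho else rho
  switch(kernel$family,
    rbf = 2 * pi * rho^2 * exp(-0.5 * rho^2 * omega^2),
    matern52 = {
      nu <- 2.5; d <- 2
      # S(w) = C * (2 nu / rho^2 + w^2)^-(nu + d/2) with
      # C = 2^d pi^(d/2) Gamma(nu + d/2) (2 nu)^nu / (Gamma(nu) rho^(2 nu))
      C <- 2^d * pi^(d / 2) * gamma(nu + d / 2) * (2 * nu)^nu /
        (gamma(nu) * rho^(2 * nu))
      C * (2 * nu / rho^2 + omega^2)^(-(nu + d / 2))
    },
    stop("unknown kernel family: ", kernel$family))
}

# Normalized mode weights w_k for a basis and kernel; see header comment.
spectral_weights <- function(basis, kernel) {
  S <- spectral_density(kernel, sqrt(pmax(basis$values, 0)))
  sqrt(S / sum(S))
}

#' Evaluate a latent field from basis coefficients
#'
#' `theta(x) = m + (alpha / |Phi_1|) sum_k eta_k w_k phi_k(x)` where
#' `|Phi_1| = 1/sqrt(area)` is the constant value of the first
#' mass-orthonormal eigenfunction and `w_k` are normalized spectral
#' weights (see [spectral_density()]).
#'
#' @param basis An `lb_basis`.
#' @param kernel A [kernel_spec()].
#' @param m Field mean.
#' @param eta Coefficient vector of length `K` (standard normal a priori).
#' @param vertices Optional vertex subset (default all).
#' @return Field values at the requested vertices.
#' @export
evaluate_field <- function(basis, kernel, m, eta, vertices = NULL) {
  K <- length(basis$values)
  if (length(eta) != K) {
    stop("eta must have length K = ", K)
  }
  w <- spectral_weights(basis, kernel)
  phi <- if (is.null(vertices)) basis$vectors else
    basis$vectors[vertices, , drop = FALSE]
  pre <- kernel$alpha * sqrt(basis$area) # alpha / |Phi_1|
  drop(m + pre * (phi %*% (w * eta)))
}

#' Draw a random field from the manifold GP prior
#'
#' Draws `eta ~ N(0, I)` with the given seed and evaluates the field; a
#' pure function of `(basis, kernel, m, seed)`.
#'
#' @inheritParams evaluate_field
#' @param seed Integer seed.
#' @return Field values at all vertices, with the drawn `eta` as
#'   attribute `"eta"`.
#' @export
sample_field <- function(basis, kernel, m = 0, seed = 1) {
  K <- length(basis$values)
  w <- spectral_weights(basis, kernel)
  if (K >= 2 && w[K]^2 > 0.01 * max(w[2]^2, .Machine$double.eps)) {
    warning("spectral weight of mode K is not negligible; ",
            "consider more eigenpairs for this lengthscale")
  }
  eta <- withr::with_seed(seed, stats::rnorm(K))
  out <- evaluate_field(basis, kernel, m, eta)
  attr(out, "eta") <- eta
  out
}

#' Calibrate kernel lengthscale units to physical distance
#'
#' Draws many GP samples, computes empirical correlations between vertex
#' pairs, and least-squares fits the kernel correlation function of
#' geodesic (edge-graph) distance, `corr(d) = k(d / (s * rho))`,
#' returning the distance scale `s` in mm per unit of `rho`.
#'
#' @param mesh A `tri_mesh`.
#' @param basis An `lb_basis` for the mesh.
#' @param kernel A [kernel_spec()]; `rho` should be small enough that
#'   correlations approach zero for distant vertex pairs.
#' @param n_samples Number of GP draws (default 1000).
#' @param n_pairs Number of random vertex pairs (default 2000).
#' @param seed Integer seed.
#' @return The fitted scale in mm per lengthscale unit.
#' @export
calibrate_lengthscale_mm <- function(mesh, basis, kernel,
                                     n_samples = 1000, n_pairs = 2000,
                                     seed = 1) {
  n <- basis$n_vertices
  draws <- withr::with_seed(seed, {
    eta <- matrix(stats::rnorm(length(basis$values) * n_samples),
                  ncol = n_samples)
    pi1 <- sample.int(n, min(60, n))
    list(eta = eta, anchors = pi1)
  })
  w <- spectral_weights(basis, kernel)
  fields <- basis$vectors %*% (w * draws$eta) # n x n_samples, alpha = 1 scale
  anchors <- draws$anchors
  gd <- mesh_geodesics(mesh, from = anchors)
  # center and correlate anchor rows against all vertices
  fa <- fields[anchors, , drop = FALSE]
  fa <- fa - rowMeans(fa)
  fc <- fields - rowMeans(fields)
  sda <- sqrt(rowSums(fa^2))
  sdc <- sqrt(rowSums(fc^2))
  # subsample pairs
  set.seed(seed + 1)
  ai <- sample.int(length(anchors), n_pairs, replace = TRUE)
  vj <- sample.int(n, n_pairs, replace = TRUE)
  corr <- rowSums(fa[ai, , drop = FALSE] * fc[vj, , drop = FALSE]) /
    (sda[ai] * sdc[vj])
  d <- gd[cbind(ai, vj)]
  ok <- is.finite(corr) & is.finite(d)
  corr <- corr[ok]; d <- d[ok]
  if (stats::quantile(corr, 0.05) > 0.5) {
    stop("correlations do not decay on this mesh; use a smaller rho")
  }
  kf <- function(r) {
    switch(kernel$family,
           rbf = exp(-0.5 * r^2),
           matern52 = {
             u <- sqrt(5) * r
             (1 + u + u^2 / 3) * exp(-u)
           })
  }
  obj <- function(s) sum((corr - kf(d / (s * kernel$rho)))^2)
  dmax <- max(d)
  stats::optimize(obj, interval = c(1e-3, dmax / kernel$rho))$minimum
}

#' Transfer a per-vertex field between meshes
#'
#' Inverse-distance-weighted interpolation from the vertices of a coarse
#' mesh to those of a fine mesh; exact at coincident vertices.
#'
#' @param values Field values at `coarse` vertices.
#' @param coarse,fine `tri_mesh` objects that overlap geometrically.
#' @param radius Interpolation radius in mm (default: 3x the median
#'   coarse edge length); fine vertices with no coarse vertex inside the
#'   radius are assigned the nearest value, with a warning.
#' @param power Inverse-distance exponent (default 2).
#' @return Field values at `fine` vertices.
#' @export
transfer_field <- function(values, coarse, fine, radius = NULL, power = 2) {
  vc <- coarse$vertices; vf <- fine$vertices
  stopifnot(length(values) == nrow(vc))
  if (is.null(radius)) {
    g <- mesh_edge_graph(coarse)
    radius <- 3 * stats::median(igraph::E(g)$weight)
  }
  out <- numeric(nrow(vf))
  n_far <- 0
  for (i in seq_len(nrow(vf))) {
    d2 <- (vc[, 1] - vf[i, 1])^2 + (vc[, 2] - vf[i, 2])^2 +
      (vc[, 3] - vf[i, 3])^2
    jmin <- which.min(d2)
    if (d2[jmin] < 1e-20) {
      out[i] <- values[jmin]
      next
    }
    sel <- which(d2 <= radius^2)
    if (!length(sel)) {
      n_far <- n_far + 1
      out[i] <- values[jmin]
    } else {
      w <- 1 / d2[sel]^(power / 2)
      out[i] <- sum(w * values[sel]) / sum(w)
    }
  }
  if (n_far > 0) {
    warning(n_far, " fine vertices beyond the interpolation radius; ",
            "nearest-neighbour values used")
  }
  out
}
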