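# Post-processing of posterior samples: latent fields on all vertices,
# summaries, and the physiological-range constraint projection.

#' Evaluate posterior field samples on the whole mesh
#'
#' Evaluates both latent fields for every retained draw, and computes
#' pointwise summaries (mean, sd) and the maximum a posteriori draw.
#'
#' @param samples A `posterior_sample_set` from [run_mcmc()].
#' @param basis The `lb_basis` used for calibration.
#' @param K Number of eigenfunctions per field (must match the sampler).
#' @param kernel_family Kernel family used in the posterior closure.
#' @return Object of class `posterior_fields`: arrays `theta1`, `theta2`
#'   (vertices x draws), summary matrices `mean`, `sd` (vertices x 2),
#'   `map_draw` index and `map` (vertices x 2).
#' @export
posterior_fields <- function(samples, basis, K = 24, kernel_family = "rbf") {
  stopifnot(nrow(samples$draws) >= 1)
  nd <- nrow(samples$draws)
  nv <- basis$n_vertices
  th1 <- matrix(NA_real_, nv, nd)
  th2 <- matrix(NA_real_, nv, nd)
  for (i in seq_len(nd)) {
    psi <- psi_unpack(samples$draws[i, ], K)
    for (l in 1:2) {
      kr <- kernel_spec(kernel_family, rho = psi[[l]]$rho,
                        alpha = psi[[l]]$alpha)
      v <- evaluate_field(sub_basis(basis, K), kr, psi[[l]]$m, psi[[l]]$eta)
      if (l == 1) th1[, i] <- v else th2[, i] <- v
    }
  }
  map_draw <- which.max(samples$lp)
  structure(list(
    theta1 = th1, theta2 = th2,
    mean = cbind(tau_out = rowMeans(th1), apd_max = rowMeans(th2)),
    sd = cbind(tau_out = row_sds(th1), apd_max = row_sds(th2)),
    map_draw = map_draw,
    map = cbind(tau_out = th1[, map_draw], apd_max = th2[, map_draw])),
    class = "posterior_fields")
}

# row standard deviations; 0 (not NA) for a single draw
row_sds <- function(m) {
  if (ncol(m) < 2) return(rep(0, nrow(m)))
  apply(m, 1, stats::sd)
}

# first-K-modes view of a basis
sub_basis <- function(basis, K) {
  if (K == length(basis$values)) return(basis)
  structure(list(values = basis$values[seq_len(K)],
                 vectors = basis$vectors[, seq_len(K), drop = FALSE],
                 mass = basis$mass, area = basis$area,
                 n_vertices = basis$n_vertices),
            class = "lb_basis")
}

#' Constrain parameter fields to acceptable ERP
#'
#' Vertices whose surrogate-predicted ERP_S2 exceeds the ceiling have
#' both parameter values replaced by a weighted average of the values at
#' acceptable vertices, with weights `1 / d_BH^4` (biharmonic distance).
#' The replacement is iterated (the weighted average can itself land in
#' the masked region) up to `max_iter` passes; draws still offending
#' after that, or with no acceptable vertices at all, are flagged.
#'
#' @param theta1,theta2 Matrices (vertices x draws) of tau_out and
#'   apd_max values (vectors are treated as a single draw).
#' @param surrogates An `erp_surrogates` object.
#' @param basis An `lb_basis` (for biharmonic distances).
#' @param ceiling_ms ERP_S2 ceiling (default: the surrogates' ceiling).
#' @param max_iter Maximum constraint passes per draw (default 10).
#' @return List with constrained `theta1`, `theta2`, `erp_s2`
#'   (recomputed ERP_S2), `n_replaced` (per draw), and `invalid`
#'   (logical per draw: constraint could not be satisfied).
#' @export
constrain_fields <- function(theta1, theta2, surrogates, basis,
                             ceiling_ms = NULL, max_iter = 10) {
  if (is.null(dim(theta1))) theta1 <- matrix(theta1, ncol = 1)
  if (is.null(dim(theta2))) theta2 <- matrix(theta2, ncol = 1)
  if (is.null(ceiling_ms)) ceiling_ms <- surrogates$ceiling_ms
  nd <- ncol(theta1)
  nv <- nrow(theta1)
  n_replaced <- integer(nd)
  invalid <- logical(nd)
  for (i in seq_len(nd)) {
    t1 <- theta1[, i]; t2 <- theta2[, i]
    for (pass in seq_len(max_iter)) {
      erp <- predict_erp(surrogates, t1, t2, "f1")
      bad <- which(erp > ceiling_ms)
      if (!length(bad)) break
      good <- which(erp <= ceiling_ms)
      if (!length(good)) {
        invalid[i] <- TRUE
        break
      }
      if (pass == 1) n_replaced[i] <- length(bad)
      for (b in bad) {
        d <- biharmonic_distance(basis, b, good)
        w <- 1 / pmax(d, 1e-12)^4
        t1[b] <- sum(w * t1[good]) / sum(w)
        t2[b] <- sum(w * t2[good]) / sum(w)
      }
    }
    erp <- predict_erp(surrogates, t1, t2, "f1")
    if (any(erp > ceiling_ms) && !invalid[i]) invalid[i] <- TRUE
    theta1[, i] <- t1; theta2[, i] <- t2
  }
  erp_s2 <- matrix(NA_real_, nv, nd)
  for (i in seq_len(nd)) {
    erp_s2[, i] <- predict_erp(surrogates, theta1[, i], theta2[, i], "f1")
  }
  list(theta1 = theta1, theta2 = theta2, erp_s2 = erp_s2,
       n_replaced = n_replaced, invalid = invalid)
}

#' ERP samples from posterior parameter fields
#'
#' @param fields A `posterior_fields` object (or list with `theta1`,
#'   `theta2` matrices).
#' @param surrogates An `erp_surrogates` object.
#' @return List with `erp_s2`, `erp_s3` (vertices x draws) and summary
#'   `mean`/`sd` matrices (vertices x 2) plus `map` predictions.
#' @export
posterior_erp <- function(fields, surrogates) {
  nd <- ncol(fields$theta1)
  nv <- nrow(fields$theta1)
  e2 <- matrix(NA_real_, nv, nd)
  e3 <- matrix(NA_real_, nv, nd)
  for (i in seq_len(nd)) {
    e2[, i] <- predict_erp(surrogates, fields$theta1[, i],
                           fields$theta2[, i], "f1")
    e3[, i] <- predict_erp(surrogates, fields$theta1[, i],
                           fields$theta2[, i], "f2")
  }
  out <- list(erp_s2 = e2, erp_s3 = e3,
              mean = cbind(erp_s2 = rowMeans(e2), erp_s3 = rowMeans(e3)),
              sd = cbind(erp_s2 = row_sds(e2), erp_s3 = row_sds(e3)))
  if (!is.null(fields$map_draw)) {
    out$map <- cbind(erp_s2 = e2[, fields$map_draw],
                     erp_s3 = e3[, fields$map_draw])
  }
  out
}
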