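# Interval ("top-hat") likelihood for ERP observations, hyperparameter
# priors, and the log posterior over the latent-field hyperparameters
# psi = (m_1, m_2, alpha_1, alpha_2, rho_1, rho_2, eta_1, eta_2).
#
# An S1S2-type protocol only brackets ERP inside one scan interval
# [I, I + width].  The exact likelihood is a top-hat on that interval;
# it is approximated by an equal-weight mixture of N normals with sd
# equal to the sub-interval width s = width / N, centered at
# c_i = I + (i - 1/2) s.  With N = width (so s = 1 ms) the mixture is
# flat in the interval interior, falls smoothly at the edges, and has
# infinite support so gradient-based MCMC never sees -Inf.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Smoothed top-hat log likelihood of an interval observation
#'
#' @param pred Predicted ERP (ms); vectorized.
#' @param lower Interval lower bound I (ms).
#' @param width Interval width (ms, > 0).
#' @param N Number of mixture components (default `round(width)`, giving
#'   unit-width sub-intervals).
#' @return Log density at `pred` (finite for any finite `pred`).
#' @export
tophat_loglik <- function(pred, lower, width, N = NULL) {
  stopifnot(width > 0)
  if (is.null(N)) N <- max(1L, as.integer(round(width)))
  s <- width / N
  centers <- lower + (seq_len(N) - 0.5) * s
  vapply(pred, function(p) {
    lse <- logsumexp(-0.5 * ((p - centers) / s)^2)
    lse - log(N) - 0.5 * log(2 * pi * s^2)
  }, numeric(1))
}

# log density and derivative wrt pred, vectorized over pred
tophat_loglik_grad <- function(pred, lower, width, N = NULL) {
  stopifnot(width > 0)
  if (is.null(N)) N <- max(1L, as.integer(round(width)))
  s <- width / N
  centers <- lower + (seq_len(N) - 0.5) * s
  val <- numeric(length(pred))
  grad <- numeric(length(pred))
  for (i in seq_along(pred)) {
    z <- -0.5 * ((pred[i] - centers) / s)^2
    m <- max(z)
    ez <- exp(z - m)
    sez <- sum(ez)
    val[i] <- m + log(sez) - log(N) - 0.5 * log(2 * pi * s^2)
    grad[i] <- sum(ez * (centers - pred[i])) / (sez * s^2)
  }
  list(value = val, grad = grad)
}

#' ERP interval observations
#'
#' @param vertex Mesh vertex indices (1-based).
#' @param protocol Character, `"S2"` or `"S3"` per observation.
#' @param lower Interval lower bounds I (ms).
#' @param width Interval widths (ms).
#' @return Data frame of class `erp_observations`.
#' @export
erp_observations <- function(vertex, protocol, lower, width) {
  stopifnot(all(width > 0), all(lower > 0),
            all(protocol %in% c("S2", "S3")))
  structure(data.frame(vertex = as.integer(vertex),
                       protocol = as.character(protocol),
                       lower = lower, width = width),
            class = c("erp_observations", "data.frame"))
}

#' Hyperparameter priors and bounds
#'
#' Default priors: `rho ~ InvGamma(1.01, 20)`, `alpha ~ InvGamma(1, 5)`,
#' `m` flat (improper), `eta_k ~ N(0, 1)`.  The flat prior on the means
#' is truncated to the physical parameter range extended by 50% on each
#' side, which guarantees a proper posterior when no data constrain a
#' field.
#'
#' @param m_bounds List of two `c(lo, hi)` bounds for the two field
#'   means; default: tau_out and apd_max ranges widened by 50%.
#' @param rho_shape,rho_scale Inverse-gamma parameters for lengthscales.
#' @param alpha_shape,alpha_scale Inverse-gamma parameters for amplitudes.
#' @return List of prior settings.
#' @export
hyper_priors <- function(m_bounds = NULL, rho_shape = 1.01, rho_scale = 20,
                         alpha_shape = 1, alpha_scale = 5) {
  if (is.null(m_bounds)) {
    widen <- function(r) {
      w <- 0.5 * (r[2] - r[1])
      c(r[1] - w, r[2] + w)
    }
    rng <- ep_param_ranges()
    m_bounds <- list(widen(rng$tau_out), widen(rng$apd_max))
  }
  list(m_bounds = m_bounds, rho_shape = rho_shape, rho_scale = rho_scale,
       alpha_shape = alpha_shape, alpha_scale = alpha_scale)
}

dinvgamma_log <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

#' Log prior density of the hyperparameter vector
#'
#' @param psi List with per-field components `m`, `alpha`, `rho`, `eta`
#'   (each field a list), e.g. `psi$field1$alpha`.
#' @param priors A [hyper_priors()] list.
#' @return Log density (the flat mean prior contributes 0 inside its
#'   bounds, `-Inf` outside; non-positive `alpha`/`rho` give `-Inf`).
#' @export
log_prior <- function(psi, priors = hyper_priors()) {
  lp <- 0
  for (l in 1:2) {
    f <- psi[[l]]
    if (f$alpha <= 0 || f$rho <= 0) return(-Inf)
    b <- priors$m_bounds[[l]]
    if (f$m < b[1] || f$m > b[2]) return(-Inf)
    lp <- lp + dinvgamma_log(f$rho, priors$rho_shape, priors$rho_scale) +
      dinvgamma_log(f$alpha, priors$alpha_shape, priors$alpha_scale) +
      sum(stats::dnorm(f$eta, log = TRUE))
  }
  lp
}

# d log S / d log rho at fixed eigenvalues; per kernel family
dlogS_dlogrho <- function(family, rho, lambda) {
  switch(family,
         rbf = 2 - rho^2 * lambda,
         matern52 = -5 + 35 / (5 + lambda * rho^2),
         stop("unknown kernel family"))
}

# Pack / unpack the unconstrained sampling vector
# z = (m1, log a1, log r1, eta1[K], m2, log a2, log r2, eta2[K])
psi_pack <- function(psi, K) {
  unlist(lapply(1:2, function(l) {
    f <- psi[[l]]
    c(f$m, log(f$alpha), log(f$rho), f$eta)
  }))
}

psi_unpack <- function(z, K) {
  stopifnot(length(z) == 2 * (3 + K))
  lapply(0:1, function(l) {
    off <- l * (3 + K)
    list(m = z[off + 1], alpha = exp(z[off + 2]), rho = exp(z[off + 3]),
         eta = z[off + 3 + seq_len(K)])
  })
}

#' Build the log-posterior closure for calibration
#'
#' Returns a function of the unconstrained parameter vector
#' `z = (m_1, log alpha_1, log rho_1, eta_1, m_2, log alpha_2,
#' log rho_2, eta_2)` computing the log posterior (with log-scale
#' Jacobians) and its analytic gradient.  Field 1 is tau_out, field 2 is
#' apd_max; ERP predictions go through the surrogate functions and each
#' observation contributes a smoothed top-hat term.  Observations with a
#' missing protocol at a site simply do not appear (their factor is 1).
#'
#' @param observations An [erp_observations()] data frame.
#' @param basis An `lb_basis` (its first `K` modes are used).
#' @param surrogates An `erp_surrogates` object.
#' @param K Number of eigenfunctions per field (default 24).
#' @param kernel_family Kernel for both fields (default `"rbf"`).
#' @param priors A [hyper_priors()] list.
#' @return Function `z -> list(value, grad)`; also usable for the MAP.
#' @export
make_log_posterior <- function(observations, basis, surrogates, K = 24,
                               kernel_family = "rbf",
                               priors = hyper_priors()) {
  stopifnot(K >= 1, K <= length(basis$values))
  obs <- as.data.frame(observations)
  if (nrow(obs) > 0 && any(obs$vertex < 1 | obs$vertex > basis$n_vertices)) {
    stop("observation vertex outside the mesh")
  }
  verts <- sort(unique(obs$vertex))
  vidx <- match(obs$vertex, verts)
  is_s2 <- obs$protocol == "S2"
  lam <- pmax(basis$values[seq_len(K)], 0)
  phi <- basis$vectors[verts, seq_len(K), drop = FALSE]
  sqrt_area <- sqrt(basis$area)
  nv <- length(verts)
  dim_z <- 2 * (3 + K)

  field_eval <- function(m, a, r, eta) {
    S <- spectral_density(kernel_family, sqrt(lam), rho = r)
    w <- sqrt(S / sum(S))
    gp <- drop(phi %*% (w * eta)) * a * sqrt_area
    dls <- dlogS_dlogrho(kernel_family, r, lam)
    dls_mean <- sum(S * dls) / sum(S)
    # derivative of the field wrt log rho
    dgp_dlr <- drop(phi %*% (w * eta * 0.5 * (dls - dls_mean))) * a * sqrt_area
    list(theta = m + gp, gp = gp, w = w, dgp_dlr = dgp_dlr)
  }

  function(z) {
    grad <- numeric(dim_z)
    if (!all(is.finite(z))) return(list(value = -Inf, grad = grad))
    psi <- psi_unpack(z, K)
    for (l in 1:2) {
      if (!is.finite(psi[[l]]$alpha) || !is.finite(psi[[l]]$rho) ||
          psi[[l]]$alpha <= 0 || psi[[l]]$rho <= 0) {
        return(list(value = -Inf, grad = grad))
      }
    }
    lp <- 0
    f1 <- field_eval(psi[[1]]$m, psi[[1]]$alpha, psi[[1]]$rho, psi[[1]]$eta)
    f2 <- field_eval(psi[[2]]$m, psi[[2]]$alpha, psi[[2]]$rho, psi[[2]]$eta)

    # prior (with log-scale Jacobian for alpha, rho)
    for (l in 1:2) {
      off <- (l - 1) * (3 + K)
      p <- psi[[l]]
      b <- priors$m_bounds[[l]]
      if (p$m < b[1] || p$m > b[2]) {
        return(list(value = -Inf, grad = grad))
      }
      lp <- lp +
        dinvgamma_log(p$rho, priors$rho_shape, priors$rho_scale) +
        log(p$rho) +
        dinvgamma_log(p$alpha, priors$alpha_shape, priors$alpha_scale) +
        log(p$alpha) +
        sum(stats::dnorm(p$eta, log = TRUE))
      grad[off + 2] <- -priors$alpha_shape + priors$alpha_scale / p$alpha
      grad[off + 3] <- -priors$rho_shape + priors$rho_scale / p$rho
      grad[off + 3 + seq_len(K)] <- -p$eta
    }

    if (nrow(obs) > 0) {
      sg2 <- predict_erp_grad(surrogates, f1$theta, f2$theta, "f1")
      sg3 <- predict_erp_grad(surrogates, f1$theta, f2$theta, "f2")
      pred <- ifelse(is_s2, sg2$value[vidx], sg3$value[vidx])
      d1 <- ifelse(is_s2, sg2$d_tau_out[vidx], sg3$d_tau_out[vidx])
      d2 <- ifelse(is_s2, sg2$d_apd_max[vidx], sg3$d_apd_max[vidx])
      dll <- numeric(nrow(obs))
      for (i in seq_len(nrow(obs))) {
        tl <- tophat_loglik_grad(pred[i], obs$lower[i], obs$width[i])
        lp <- lp + tl$value
        dll[i] <- tl$grad
      }
      # accumulate d lp / d theta_l at each observed vertex
      dth1 <- tapply(dll * d1, vidx, sum)
      dth2 <- tapply(dll * d2, vidx, sum)
      g1 <- numeric(nv); g2 <- numeric(nv)
      g1[as.integer(names(dth1))] <- dth1
      g2[as.integer(names(dth2))] <- dth2
      for (l in 1:2) {
        off <- (l - 1) * (3 + K)
        fl <- if (l == 1) f1 else f2
        gl <- if (l == 1) g1 else g2
        p <- psi[[l]]
        grad[off + 1] <- grad[off + 1] + sum(gl)
        grad[off + 2] <- grad[off + 2] + sum(gl * fl$gp)
        grad[off + 3] <- grad[off + 3] + sum(gl * fl$dgp_dlr)
        grad[off + 3 + seq_len(K)] <- grad[off + 3 + seq_len(K)] +
          drop(crossprod(phi, gl)) * fl$w * p$alpha * sqrt_area
      }
    }
    list(value = lp, grad = grad)
  }
}

#' Evaluate the log posterior for a structured hyperparameter list
#'
#' Convenience wrapper around [make_log_posterior()] for a single
#' structured `psi` (list of two fields with `m`, `alpha`, `rho`,
#' `eta`).  With zero observations this equals [log_prior()] plus the
#' log-scale Jacobian terms if `jacobian = TRUE`, or exactly
#' [log_prior()] if `FALSE`.
#'
#' @inheritParams make_log_posterior
#' @param psi Structured hyperparameter list.
#' @param jacobian Include the log-transform Jacobian (default FALSE).
#' @return Log posterior value.
#' @export
log_posterior <- function(psi, observations, basis, surrogates, K = 24,
                          kernel_family = "rbf", priors = hyper_priors(),
                          jacobian = FALSE) {
  lpg <- make_log_posterior(observations, basis, surrogates, K,
                            kernel_family, priors)
  z <- psi_pack(psi, K)
  val <- lpg(z)$value
  if (!jacobian && is.finite(val)) {
    val <- val - log(psi[[1]]$alpha) - log(psi[[1]]$rho) -
      log(psi[[2]]$alpha) - log(psi[[2]]$rho)
  }
  val
}
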