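# Hamiltonian Monte Carlo over the unconstrained hyperparameter vector,
# with dual-averaging step-size adaptation and diagonal mass-matrix
# estimation during warm-up.  Positive parameters are sampled on the log
# scale by the posterior closure itself (Jacobian included there), so
# the sampler sees an unconstrained target with analytic gradients.

hmc_chain <- function(lp_grad, init, iterations, warmup, seed,
                      L_range = c(8, 24), target_accept = 0.8) {
  set.seed(seed)
  d <- length(init)
  z <- init
  cur <- lp_grad(z)
  if (!is.finite(cur$value)) stop("initial point has zero posterior density")
  # dual averaging state (Hoffman & Gelman 2014 defaults)
  eps <- 0.1
  mu <- log(10 * eps)
  log_eps_bar <- 0
  H_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  inv_mass <- rep(1, d)
  draws <- matrix(NA_real_, iterations, d)
  lps <- numeric(iterations)
  divergences <- 0
  adapt_buffer <- NULL
  mass_window <- c(floor(warmup * 0.4), floor(warmup * 0.8))

  for (it in seq_len(iterations)) {
    L <- sample(L_range[1]:L_range[2], 1)
    p0 <- stats::rnorm(d) / sqrt(inv_mass)
    z_new <- z
    p <- p0
    g <- cur$grad
    H0 <- -cur$value + 0.5 * sum(p0^2 * inv_mass)
    div <- FALSE
    val_new <- -Inf
    for (l in seq_len(L)) {
      p <- p + 0.5 * eps * g
      z_new <- z_new + eps * (p * inv_mass)
      prop <- lp_grad(z_new)
      if (!all(is.finite(prop$grad)) || !is.finite(prop$value)) {
        div <- TRUE
        break
      }
      g <- prop$grad
      val_new <- prop$value
      p <- p + 0.5 * eps * g
    }
    accept_prob <- 0
    if (!div) {
      H1 <- -val_new + 0.5 * sum(p^2 * inv_mass)
      dH <- H1 - H0
      if (!is.finite(dH) || dH > 50) {
        div <- TRUE
      } else {
        accept_prob <- min(1, exp(-dH))
        if (stats::runif(1) < accept_prob) {
          z <- z_new
          cur <- list(value = val_new, grad = g)
        }
      }
    }
    if (div && it > warmup) divergences <- divergences + 1
    if (it <= warmup) {
      # dual averaging
      H_bar <- (1 - 1 / (it + t0)) * H_bar +
        (target_accept - accept_prob) / (it + t0)
      log_eps <- mu - sqrt(it) / gamma * H_bar
      eta_w <- it^(-kappa)
      log_eps_bar <- eta_w * log_eps + (1 - eta_w) * log_eps_bar
      eps <- exp(log_eps)
      if (it >= mass_window[1] && it <= mass_window[2]) {
        adapt_buffer <- rbind(adapt_buffer, z)
      }
      if (it == mass_window[2] && nrow(adapt_buffer) > 10) {
        v <- apply(adapt_buffer, 2, stats::var)
        v[v < 1e-8] <- 1e-8
        inv_mass <- v / exp(mean(log(v))) # normalized diagonal metric
        # restart step-size adaptation for the new metric
        mu <- log(10 * exp(log_eps_bar))
        H_bar <- 0
        log_eps_bar <- log(exp(log_eps_bar))
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    }
    draws[it, ] <- z
    lps[it] <- cur$value
  }
  list(draws = draws, lp = lps, eps = eps, divergences = divergences)
}

split_rhat <- function(mat_list) {
  # mat_list: list of chains, each iterations x d (post-warmup)
  halves <- list()
  for (m in mat_list) {
    n <- nrow(m)
    if (n < 4) return(NA_real_)
    h <- floor(n / 2)
    halves <- c(halves, list(m[1:h, , drop = FALSE]),
                list(m[(n - h + 1):n, , drop = FALSE]))
  }
  n <- nrow(halves[[1]])
  d <- ncol(halves[[1]])
  rhat <- numeric(d)
  for (j in seq_len(d)) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) stats::var(h[, j]), numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) {
      rhat[j] <- 1
    } else {
      rhat[j] <- sqrt(((n - 1) / n * W + B / n) / W)
    }
  }
  rhat
}

ess_basic <- function(x) {
  # initial positive sequence estimator on a single pooled series
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  acf_x <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k < length(acf_x)) {
    pair <- acf_x[k] + ifelse(k + 1 <= length(acf_x), acf_x[k + 1], 0)
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  n / (1 + 2 * s)
}

#' Run Hamiltonian MCMC for the calibration posterior
#'
#' Samples the unconstrained hyperparameter vector with HMC (jittered
#' leapfrog length, dual-averaged step size, diagonal mass matrix
#' adapted during warm-up).  The first `burn_frac` of each chain is
#' discarded as burn-in and the remaining pooled samples are randomly
#' thinned (uniform subsampling without replacement) by `thin`, so the
#' default configuration (5000 iterations, 8 chains, 50% burn-in,
#' thinning factor 100) retains exactly 200 draws.
#'
#' @param lp_grad Function `z -> list(value, grad)` (from
#'   [make_log_posterior()]).
#' @param init_fn Function `(chain_index) -> z` giving initial points.
#' @param iterations Iterations per chain (default 5000).
#' @param chains Number of chains (default 8).
#' @param burn_frac Burn-in fraction (default 0.5).
#' @param thin Random thinning factor (default 100).
#' @param seed Integer seed; the run is a pure function of it.
#' @param L_range Leapfrog steps are drawn uniformly from this range.
#' @param target_accept Dual-averaging target acceptance (default 0.8).
#' @param divergence_warn Warn if the post-warmup divergent-transition
#'   fraction exceeds this (default 0.02).
#' @return Object of class `posterior_sample_set`: `draws` (retained x
#'   dim), `lp`, `provenance` (chain, iteration), `rhat`, `ess`,
#'   `divergence_frac`, `config`.
#' @export
run_mcmc <- function(lp_grad, init_fn, iterations = 5000, chains = 8,
                     burn_frac = 0.5, thin = 100, seed = 1,
                     L_range = c(8, 24), target_accept = 0.8,
                     divergence_warn = 0.02) {
  stopifnot(iterations >= 10, chains >= 1)
  warmup <- floor(iterations * burn_frac)
  res <- vector("list", chains)
  for (cc in seq_len(chains)) {
    init <- withr::with_seed(seed + 1000L * cc, init_fn(cc))
    res[[cc]] <- hmc_chain(lp_grad, init, iterations, warmup,
                           seed = seed + cc, L_range = L_range,
                           target_accept = target_accept)
  }
  kept <- lapply(res, function(r) {
    list(draws = r$draws[(warmup + 1):iterations, , drop = FALSE],
         lp = r$lp[(warmup + 1):iterations])
  })
  n_retain <- retained_draw_count(iterations, chains, burn_frac, thin)
  pool_draws <- do.call(rbind, lapply(kept, `[[`, "draws"))
  pool_lp <- unlist(lapply(kept, `[[`, "lp"))
  prov <- data.frame(
    chain = rep(seq_len(chains), each = iterations - warmup),
    iteration = rep((warmup + 1):iterations, times = chains))
  pick <- withr::with_seed(seed + 777L,
                           sort(sample.int(nrow(pool_draws), n_retain)))
  rhat <- split_rhat(lapply(kept, `[[`, "draws"))
  ess <- vapply(seq_len(ncol(pool_draws)),
                function(j) ess_basic(pool_draws[, j]), numeric(1))
  div_frac <- sum(vapply(res, `[[`, numeric(1), "divergences")) /
    (chains * (iterations - warmup))
  if (div_frac > divergence_warn) {
    warning(sprintf("divergent-transition fraction %.3f exceeds %.3f",
                    div_frac, divergence_warn))
  }
  structure(list(draws = pool_draws[pick, , drop = FALSE],
                 lp = pool_lp[pick],
                 provenance = prov[pick, ],
                 rhat = rhat, ess = ess, divergence_frac = div_frac,
                 config = list(iterations = iterations, chains = chains,
                               burn_frac = burn_frac, thin = thin,
                               seed = seed,
                               eps = vapply(res, `[[`, numeric(1), "eps"))),
            class = "posterior_sample_set")
}

#' Retained-draw bookkeeping
#'
#' `chains * iterations * (1 - burn_frac) / thin`, rounded down; the
#' default configuration (5000 x 8, 50% burn-in, thinning 100) gives
#' exactly 200.
#'
#' @param iterations,chains,burn_frac,thin MCMC configuration.
#' @return Integer retained-draw count.
#' @export
retained_draw_count <- function(iterations, chains, burn_frac = 0.5,
                                thin = 100) {
  as.integer(floor(chains * iterations * (1 - burn_frac) / thin))
}

#' @export
print.posterior_sample_set <- function(x, ...) {
  cat(sprintf("posterior_sample_set: %d draws (%d chains x %d iterations)\n",
              nrow(x$draws), x$config$chains, x$config$iterations))
  cat(sprintf("  max split-Rhat %.3f; min ESS %.0f; divergence frac %.4f\n",
              max(x$rhat), min(x$ess), x$divergence_frac))
  invisible(x)
}
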