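# Top-hat likelihood, priors, posterior closure, and the HMC sampler.

test_that("top-hat log likelihood matches a brute-force mixture sum", {
  lower <- 200; width <- 10
  pred <- lower + width / 2
  # independent direct summation of the N = 10 unit-sd normal mixture
  centers <- lower + (1:10 - 0.5)
  oracle <- log(mean(stats::dnorm(pred, centers, 1)))
  expect_equal(tophat_loglik(pred, lower, width), oracle, tolerance = 1e-12)
  # symmetric about the interval midpoint
  for (delta in c(0.3, 2.1, 7.7)) {
    expect_equal(tophat_loglik(lower + delta, lower, width),
                 tophat_loglik(lower + width - delta, lower, width),
                 tolerance = 1e-10)
  }
  # far outside: tiny but finite (infinite support)
  far <- tophat_loglik(lower + width + 20, lower, width)
  expect_lt(far, -150)
  expect_true(is.finite(far))
})

test_that("top-hat gradient matches finite differences", {
  g <- erpfield:::tophat_loglik_grad(c(198, 204.5, 213), 200, 10)
  for (i in 1:3) {
    p <- c(198, 204.5, 213)[i]
    fd <- (tophat_loglik(p + 1e-5, 200, 10) -
             tophat_loglik(p - 1e-5, 200, 10)) / 2e-5
    expect_equal(g$grad[i], fd, tolerance = 1e-6)
  }
})

test_that("observation container validates its inputs", {
  expect_error(erp_observations(1, "S4", 200, 10), "S2")
  expect_error(erp_observations(1, "S2", 200, 0), "width")
  obs <- erp_observations(c(1, 1), c("S2", "S3"), c(240, 180), 10)
  expect_s3_class(obs, "erp_observations")
  expect_equal(nrow(obs), 2)
})

test_that("priors have the documented shape", {
  # InvGamma(1.01, 20) mode at 20/2.01, via grid maximization oracle
  grid <- seq(1, 60, by = 0.001)
  dens <- erpfield:::dinvgamma_log(grid, 1.01, 20)
  expect_equal(grid[which.max(dens)], 20 / 2.01, tolerance = 1e-3)
  psi <- list(list(m = 10, alpha = 2, rho = 5, eta = c(0.5, -1)),
              list(m = 200, alpha = 10, rho = 8, eta = c(1, 0)))
  lp0 <- log_prior(psi)
  # flat prior: shifting a mean does not change the density
  psi_shift <- psi
  psi_shift[[1]]$m <- 25
  expect_equal(log_prior(psi_shift), lp0)
  # eta contributes the standard normal log density
  psi0 <- psi
  psi0[[1]]$eta <- c(0, 0)
  expect_equal(lp0 - log_prior(psi0),
               sum(stats::dnorm(c(0.5, -1), log = TRUE)) -
                 sum(stats::dnorm(c(0, 0), log = TRUE)))
  psi_bad <- psi
  psi_bad[[2]]$alpha <- -1
  expect_identical(log_prior(psi_bad), -Inf)
  # out-of-bounds mean
  psi_far <- psi
  psi_far[[1]]$m <- 1e4
  expect_identical(log_prior(psi_far), -Inf)
})

test_that("zero observations reduce the posterior to the prior", {
  b <- fx_coarse_basis()
  surr <- fx_toy_surrogates()
  obs <- erp_observations(integer(0), character(0), numeric(0), numeric(0))
  K <- 8
  psi <- list(list(m = 12, alpha = 3, rho = 7, eta = stats::rnorm(K)),
              list(m = 190, alpha = 12, rho = 9, eta = stats::rnorm(K)))
  expect_equal(log_posterior(psi, obs, b, surr, K = K), log_prior(psi))
})

test_that("analytic posterior gradient matches central finite differences", {
  set.seed(8)
  b <- fx_coarse_basis()
  surr <- fx_toy_surrogates()
  K <- 10
  obs <- erp_observations(c(3, 40, 90, 3), c("S2", "S2", "S3", "S3"),
                          c(230, 250, 190, 200), 10)
  for (fam in c("rbf", "matern52")) {
    lpg <- make_log_posterior(obs, b, surr, K = K, kernel_family = fam)
    z <- c(14, log(2.5), log(7), rnorm(K, 0, 0.6),
           195, log(18), log(11), rnorm(K, 0, 0.6))
    g <- lpg(z)
    for (i in seq_along(z)) {
      e <- numeric(length(z)); e[i] <- 5e-6
      fd <- (lpg(z + e)$value - lpg(z - e)$value) / 1e-5
      expect_equal(g$grad[i], fd, tolerance = 1e-5)
    }
  }
})

test_that("likelihood is permutation invariant and finite in the mask", {
  b <- fx_coarse_basis()
  surr <- fx_toy_surrogates(ceiling_ms = 100) # everything masked
  K <- 6
  obs <- erp_observations(c(2, 50, 80), c("S2", "S3", "S2"),
                          c(240, 190, 230), 10)
  lpg <- make_log_posterior(obs, b, surr, K = K)
  z <- c(14, log(2), log(7), numeric(K), 195, log(15), log(9), numeric(K))
  v1 <- lpg(z)$value
  expect_true(is.finite(v1)) # masked region still yields a finite value
  lpg_perm <- make_log_posterior(obs[c(3, 1, 2), ], b, surr, K = K)
  expect_equal(lpg_perm(z)$value, v1)
  # vertex bounds are checked
  expect_error(make_log_posterior(
    erp_observations(1e5, "S2", 200, 10), b, surr, K = K), "mesh")
})

test_that("HMC recovers a standard normal and is exactly reproducible", {
  lp2 <- function(z) list(value = -0.5 * sum(z^2), grad = -z)
  s <- run_mcmc(lp2, function(cc) stats::rnorm(2), iterations = 2000,
                chains = 2, thin = 4, seed = 5)
  expect_equal(nrow(s$draws), retained_draw_count(2000, 2, 0.5, 4))
  mcse <- apply(s$draws, 2, stats::sd) / sqrt(s$ess)
  expect_true(all(abs(colMeans(s$draws)) < 3 * pmax(mcse, 0.05)))
  expect_true(all(abs(apply(s$draws, 2, stats::sd) - 1) < 0.15))
  expect_lt(max(s$rhat), 1.1)
  s2 <- run_mcmc(lp2, function(cc) stats::rnorm(2), iterations = 2000,
                 chains = 2, thin = 4, seed = 5)
  expect_identical(s$draws, s2$draws)
})
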