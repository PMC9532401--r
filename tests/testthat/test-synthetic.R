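# Synthetic-experiment module: ground truths, observations, validation.

test_that("ground truths are seeded, in range, and smoother at larger rho", {
  b <- fx_coarse_basis()
  m <- fx_coarse()
  surr <- fx_toy_surrogates()
  s1 <- generate_ground_truth(m, b, surr, rho = 6, seed = 3)
  s1b <- generate_ground_truth(m, b, surr, rho = 6, seed = 3)
  expect_identical(s1$tau_out, s1b$tau_out)
  rng <- ep_param_ranges()
  expect_true(all(s1$tau_out >= rng$tau_out[1] &
                    s1$tau_out <= rng$tau_out[2]))
  expect_true(all(s1$apd_max >= rng$apd_max[1] &
                    s1$apd_max <= rng$apd_max[2]))
  expect_true(all(s1$cv_max >= rng$cv_max[1] & s1$cv_max <= rng$cv_max[2]))
  expect_true(all(s1$erp_s2 <= surr$ceiling_ms + 1e-9))
  # roughness: mean absolute neighbour difference decreases as rho doubles
  g <- igraph::as_edgelist(erpfield:::mesh_edge_graph(m))
  rough <- function(v) mean(abs(v[g[, 1]] - v[g[, 2]]))
  r_small <- mean(vapply(1:4, function(s) {
    rough(generate_ground_truth(m, b, surr, rho = 5, seed = s)$apd_max)
  }, numeric(1)))
  r_big <- mean(vapply(1:4, function(s) {
    rough(generate_ground_truth(m, b, surr, rho = 10, seed = s)$apd_max)
  }, numeric(1)))
  expect_lt(r_big, r_small)
})

test_that("interval observations bracket the truth at the scan resolution", {
  b <- fx_coarse_basis()
  m <- fx_coarse()
  surr <- fx_toy_surrogates()
  sc <- generate_ground_truth(m, b, surr, rho = 8, seed = 5)
  verts <- c(3, 50, 120)
  obs <- observe_erp(sc, verts, resolution = 10)
  expect_equal(nrow(obs), 6) # two protocols per site
  expect_true(all(obs$width == 10))
  expect_true(all(obs$true_erp > obs$lower &
                    obs$true_erp <= obs$lower + obs$width))
  # halved resolution gives nested brackets
  obs5 <- observe_erp(sc, verts, resolution = 5)
  expect_true(all(obs5$lower >= obs$lower - 1e-9))
  expect_true(all(obs5$lower + obs5$width <= obs$lower + obs$width + 1e-9))
})

test_that("validation metrics are exact for a perfect posterior", {
  b <- fx_coarse_basis()
  m <- fx_coarse()
  surr <- fx_toy_surrogates()
  sc <- generate_ground_truth(m, b, surr, rho = 8, seed = 6)
  nv <- length(sc$erp_s2)
  perfect <- list(mean = cbind(erp_s2 = sc$erp_s2, erp_s3 = sc$erp_s3),
                  sd = cbind(erp_s2 = rep(1, nv), erp_s3 = rep(1, nv)),
                  map = cbind(erp_s2 = sc$erp_s2, erp_s3 = sc$erp_s3))
  v <- validate_scenario(sc, perfect)
  expect_equal(v$rmse, 0)
  expect_equal(max(v$ise), 0)
  expect_equal(v$frac_ise_lt3, 1)
  # ISE invariant under adding a constant to truth and posterior mean
  shifted <- perfect
  shifted$mean <- perfect$mean + 7
  sc2 <- sc
  sc2$erp_s2 <- sc$erp_s2 + 7
  sc2$erp_s3 <- sc$erp_s3 + 7
  expect_equal(validate_scenario(sc2, shifted)$ise, v$ise)
})

test_that("an empty sweep configuration returns an empty table", {
  sw <- run_validation_sweep(fx_coarse(), fx_coarse_basis(),
                             fx_toy_surrogates(), lengthscales = numeric(0),
                             n_obs = integer(0))
  expect_s3_class(sw, "data.frame")
  expect_equal(nrow(sw), 0)
})
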