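# Strip simulator: resting state, trace measurement, ERP protocols.

fast_params <- function(apd = 170, tau_out = 8, cv = 0.6) {
  ep_params(cv, 0.05, tau_out, 120, apd, check = FALSE)
}

test_that("rest is a fixed point: no stimulus gives V identically zero", {
  np <- to_native(fast_params())
  out <- simulate_cable(np, numeric(0), 200, record = "all")
  expect_equal(max(abs(out$full)), 0)
  expect_equal(out$h, rep(1, cable_config()$n_nodes))
})

test_that("voltage stays in the physiological envelope away from stimulus", {
  np <- to_native(fast_params())
  cfg <- cable_config()
  out <- simulate_cable(np, 0, 400, cfg, record = "all")
  interior <- (cfg$stim_nodes + 3):cfg$n_nodes
  expect_gt(min(out$full[, interior]), -0.05)
  expect_lt(max(out$full[, interior]), 1.05)
  expect_true(all(out$h >= 0 & out$h <= 1))
})

test_that("numerical blow-up raises rather than returning garbage", {
  np <- to_native(fast_params())
  cfg <- cable_config(dt_diffusion = 4, dt_ionic = 4) # unstable reaction step
  expect_error(simulate_cable(np, 0, 100, cfg), "diverged")
})

test_that("dt_ionic must divide dt_diffusion", {
  expect_error(cable_config(dt_diffusion = 0.1, dt_ionic = 0.03), "divide")
})

test_that("measure_trace handles flat, synthetic, and simulated traces", {
  flat <- measure_trace(0:100, rep(0, 101))
  expect_false(flat$activated)
  expect_true(is.na(flat$apd90))
  # piecewise-linear pulse: rises through 0.7 at t = 5, falls through 0.1
  # at t = 205, so apd90 = 200 ms exactly
  tt <- c(0, 5, 6, 100, 205, 210)
  vv <- c(0, 0.7, 1, 0.5, 0.1, 0)
  m <- measure_trace(tt, vv)
  expect_true(m$activated)
  expect_equal(m$lat, 5)
  expect_equal(m$apd90, 200)
  # simulated beat: monotone APD thresholds
  np <- to_native(fast_params())
  out <- simulate_cable(np, 0, 350)
  ms <- measure_trace(out$times, out$trace[, 1])
  expect_true(ms$activated)
  expect_true(ms$apd20 < ms$apd30 && ms$apd30 < ms$apd50 &&
                ms$apd50 < ms$apd90)
})

test_that("ERP bracket is consistent and refinable", {
  p <- fast_params()
  proto <- pacing_protocol("S1S2", resolution = 10, scan_from = 300)
  r <- erp_s1s2(p, proto)
  expect_equal(r$status, "ok")
  expect_equal(diff(r$bracket), proto$resolution)
  expect_true(r$erp > r$bracket[1] && r$erp <= r$bracket[2])
  # half the resolution: bracket nested inside the original
  proto5 <- pacing_protocol("S1S2", resolution = 5, scan_from = 300)
  r5 <- erp_s1s2(p, proto5)
  expect_true(r5$bracket[1] >= r$bracket[1] - 1e-9)
  expect_true(r5$bracket[2] <= r$bracket[2] + 1e-9)
})

test_that("refined ERP is stable when the ionic step is halved", {
  proto <- pacing_protocol("S1S2", scan_from = 300)
  for (apd in c(150, 175, 200)) {
    p <- fast_params(apd = apd)
    e1 <- erp_s1s2(p, proto, cable_config(), refine_ms = 0.25)$erp
    e2 <- erp_s1s2(p, proto, cable_config(dt_ionic = 0.01),
                   refine_ms = 0.25)$erp
    expect_lt(abs(e1 - e2), 1)
  }
})

test_that("ERP_S2 is non-decreasing in apd_max", {
  proto <- pacing_protocol("S1S2", scan_from = 320)
  erps <- vapply(c(150, 180, 210), function(apd) {
    erp_s1s2(fast_params(apd = apd), proto)$erp
  }, numeric(1))
  expect_true(all(diff(erps) >= 0))
})

test_that("ERP_S3 <= ERP_S2 and S1S2S3 fails when the S2 beat cannot capture", {
  proto2 <- pacing_protocol("S1S2")
  proto3 <- pacing_protocol("S1S2S3")
  for (apd in c(170, 200)) {
    p <- fast_params(apd = apd)
    r2 <- erp_s1s2(p, proto2)
    r3 <- erp_s1s2s3(p, proto3)
    expect_equal(diff(r3$bracket), proto3$resolution)
    expect_lte(r3$erp, r2$erp)
  }
  # ERP_S2 far above the 300 ms S2 interval: protocol invalid
  expect_error(erp_s1s2s3(ep_params(0.6, 0.05, 25, 120, 240, check = FALSE)),
               "S2 beat fails to capture")
})

test_that("training tables are complete, deterministic, and CV-insensitive", {
  design <- data.frame(cv_max = c(0.4, 1.2), tau_out = 8, apd_max = 165)
  tb1 <- generate_training_table(design)
  tb2 <- generate_training_table(design)
  expect_equal(nrow(tb1), 2)
  expect_identical(tb1, tb2) # bit-for-bit reproducible
  expect_equal(tb1$tau_in, c(0.05, 0.05))
  expect_equal(tb1$tau_open, c(120, 120))
  expect_true(all(tb1$flag_s2 == "ok"))
  # cv_max has a negligible effect on ERP (within the scan resolution)
  expect_lt(abs(tb1$erp_s2[1] - tb1$erp_s2[2]), 10)
})
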