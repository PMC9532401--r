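# Surrogate fitting, prediction, and GAM sensitivity indices.

test_that("fitting recovers a known bivariate cubic exactly", {
  set.seed(1)
  to <- runif(60, 1, 30); ap <- runif(60, 120, 270)
  x <- 2 * (to - 1) / 29 - 1; y <- 2 * (ap - 120) / 150 - 1
  truth <- c(200, 20, 30, 5, -8, 3, 2, 1, -2, 4)
  mono <- cbind(1, x, y, x^2, x * y, y^2, x^3, x^2 * y, x * y^2, y^3)
  tb <- data.frame(tau_out = to, apd_max = ap,
                   erp_s2 = drop(mono %*% truth),
                   erp_s3 = drop(mono %*% (truth * 0.8)))
  # keep all rows in range by lifting the ceiling
  surr <- fit_surrogates(tb, ceiling_ms = 1e6)
  # ranges come from the data, so compare predictions, not raw coefs
  expect_equal(predict_erp(surr, to, ap, "f1"), tb$erp_s2,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(surr$f1$rms, 1e-8)
  expect_lt(surr$f2$rms, 1e-8)
})

test_that("degenerate training inputs are rejected", {
  tb <- data.frame(tau_out = rep(10, 30), apd_max = seq(120, 270, length.out = 30),
                   erp_s2 = seq(150, 250, length.out = 30),
                   erp_s3 = seq(120, 200, length.out = 30))
  expect_error(fit_surrogates(tb, ceiling_ms = 1e6), "rank-deficient")
  expect_error(fit_surrogates(tb[1:10, ], ceiling_ms = 1e6), "fewer than 20")
})

test_that("prediction evaluates the polynomial with flags, not errors", {
  surr <- fx_toy_surrogates()
  x <- 2 * (12 - 1) / 29 - 1
  y <- 2 * (200 - 120) / 150 - 1
  manual <- 220 + 25 * x + 35 * y + 5 * x * y
  expect_equal(as.numeric(predict_erp(surr, 12, 200, "f1")), manual)
  # continuity
  p0 <- predict_erp(surr, 12, 200, "f2")
  p1 <- predict_erp(surr, 12 + 1e-6, 200 + 1e-6, "f2")
  expect_lt(abs(p1 - p0), 1e-4)
  # masked where predicted ERP_S2 exceeds the ceiling; flagged outside
  # the training rectangle; both without raising
  hi <- predict_erp(surr, 30, 270, "f2")
  expect_true(attr(hi, "masked"))
  expect_true(is.finite(hi))
  out <- predict_erp(surr, 45, 200, "f1")
  expect_true(attr(out, "extrapolated"))
  expect_warning(predict_erp(surr, 45, 200, "f1", warn_extrapolation = TRUE),
                 "training rectangle")
})

test_that("the ERP_S2 ceiling governs which rows are fit", {
  set.seed(2)
  to <- runif(60, 1, 30); ap <- runif(60, 120, 270)
  erp2 <- 140 + 3 * to + 0.45 * ap # a mix of rows below and above 280
  tb <- data.frame(tau_out = to, apd_max = ap, erp_s2 = erp2,
                   erp_s3 = 100 + 0.4 * ap)
  both <- fit_surrogates(tb, ceiling_ms = 280, mask_s2_fit = TRUE)
  s3only <- fit_surrogates(tb, ceiling_ms = 280, mask_s2_fit = FALSE)
  expect_equal(both$f2$n, s3only$f2$n)       # f2 always masked
  expect_gt(s3only$f1$n, both$f1$n)          # f1 keeps the tall rows
  expect_equal(both$f1$n, sum(erp2 <= 280))
})

test_that("surrogates agree with held-out strip-simulator runs", {
  surr <- fx_surrogates()
  set.seed(5)
  pts <- data.frame(tau_out = runif(6, 5, 22), apd_max = runif(6, 150, 225))
  proto2 <- pacing_protocol("S1S2")
  proto3 <- pacing_protocol("S1S2S3")
  sim2 <- sim3 <- pred2 <- pred3 <- numeric(0)
  for (i in seq_len(nrow(pts))) {
    p1 <- predict_erp(surr, pts$tau_out[i], pts$apd_max[i], "f1")
    if (p1 > 270) next # stay clear of the discontinuity ceiling
    p <- ep_params(0.6, 0.05, pts$tau_out[i], 120, pts$apd_max[i],
                   check = FALSE)
    sim2 <- c(sim2, erp_s1s2(p, proto2)$erp)
    sim3 <- c(sim3, erp_s1s2s3(p, proto3)$erp)
    pred2 <- c(pred2, p1)
    pred3 <- c(pred3, predict_erp(surr, pts$tau_out[i], pts$apd_max[i], "f2"))
  }
  expect_gte(length(sim2), 4)
  expect_lt(max(abs(sim2 - pred2), abs(sim3 - pred3)), 8)
  expect_lt(sqrt(mean(c(sim2 - pred2, sim3 - pred3)^2)), 2.5)
})

test_that("surrogate JSON serialization round-trips", {
  surr <- fx_toy_surrogates()
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogates(surr, path)
  back <- read_surrogates(path)
  expect_equal(predict_erp(back, c(5, 20), c(150, 250), "f2"),
               predict_erp(surr, c(5, 20), c(150, 250), "f2"))
  expect_equal(back$ceiling_ms, surr$ceiling_ms)
})

test_that("sensitivity indices decompose variance as expected", {
  set.seed(3)
  n <- 300
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  # pure x1 signal
  r1 <- gam_sensitivity(X, data.frame(y = sin(2 * pi * X$x1)))
  expect_gt(r1$indices["x1", "y"], 0.95)
  expect_lt(max(r1$indices[c("x2", "x3"), "y"]), 0.05)
  # additive equal shares: analytic indices are 0.5 each
  r2 <- gam_sensitivity(X[1:2], data.frame(y = X$x1 + X$x2))
  expect_equal(unname(r2$indices[, "y"]), c(0.5, 0.5), tolerance = 0.06)
  expect_true(all(r2$indices <= 1.02))
  # zero-variance output reported as absent
  r3 <- gam_sensitivity(X, data.frame(y = rep(1, n)))
  expect_true(all(is.na(r3$indices)))
})

test_that("tau_out and apd_max dominate ERP sensitivity on the mMS table", {
  tb <- attr(fx_surrogates(), "table")
  ok <- tb$flag_s2 == "ok" & tb$flag_s3 == "ok"
  rep <- gam_sensitivity(tb[ok, c("cv_max", "tau_out", "apd_max")],
                         tb[ok, c("erp_s2", "erp_s3")])
  for (out in c("erp_s2", "erp_s3")) {
    expect_gt(min(rep$indices[c("tau_out", "apd_max"), out]),
              rep$indices["cv_max", out])
  }
  # most clinically plausible ERP_S2 values fall in the 170-270 ms band
  expect_gt(mean(tb$erp_s2[ok] >= 170 & tb$erp_s2[ok] <= 270), 0.4)
  expect_true(stats::median(tb$erp_s2[ok]) > 170 &&
                stats::median(tb$erp_s2[ok]) < 290)
})
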