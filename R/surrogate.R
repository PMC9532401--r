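# Polynomial surrogate functions mapping local EP parameters to ERP, and
# GAM-based variance sensitivity indices.
#
# f1 predicts ERP_S2 and f2 predicts ERP_S3, both as complete bivariate
# cubics (10 monomials) in (tau_out, apd_max) standardized to [-1, 1].
# Training rows with ERP_S2 above the discontinuity ceiling (280 ms) are
# discarded before fitting; the same ceiling defines the validity mask
# used when evaluating f2.

cubic_monomials <- function(x, y) {
  cbind(1, x, y, x^2, x * y, y^2, x^3, x^2 * y, x * y^2, y^3)
}

cubic_monomials_dx <- function(x, y) {
  cbind(0, 1, 0, 2 * x, y, 0, 3 * x^2, 2 * x * y, y^2, 0)
}

cubic_monomials_dy <- function(x, y) {
  cbind(0, 0, 1, 0, x, 2 * y, 0, x^2, 2 * x * y, 3 * y^2)
}

standardize <- function(v, r) 2 * (v - r[1]) / (r[2] - r[1]) - 1

#' Fit ERP surrogate functions
#'
#' Least-squares fit of the two cubic surrogates from a training table
#' produced by [generate_training_table()].  Rows whose ERP_S2 exceeds
#' `ceiling_ms` are discarded before fitting (by default for both fits;
#' the discontinuity is in the ERP_S3 response, set `mask_s2_fit =
#' FALSE` to apply the discard only to f2).  Rows with failed protocol
#' flags are dropped with a count.
#'
#' @param table Data frame with columns `tau_out`, `apd_max`, `erp_s2`,
#'   `erp_s3` (and optional `flag_s2`, `flag_s3` status columns).
#' @param ceiling_ms Validity ceiling on ERP_S2 (default 280).
#' @param mask_s2_fit Apply the ceiling discard to the ERP_S2 fit as
#'   well (default TRUE).
#' @return Object of class `erp_surrogates`: list with `f1`, `f2`, each
#'   containing `coef` (10 monomial coefficients), `ranges`
#'   (standardization), `rms` (training residual RMS), plus
#'   `ceiling_ms` and row bookkeeping.
#' @export
fit_surrogates <- function(table, ceiling_ms = 280, mask_s2_fit = TRUE) {
  tb <- as.data.frame(table)
  stopifnot(all(c("tau_out", "apd_max", "erp_s2", "erp_s3") %in% names(tb)))
  ok2 <- is.finite(tb$erp_s2)
  ok3 <- ok2 & is.finite(tb$erp_s3)
  if ("flag_s2" %in% names(tb)) ok2 <- ok2 & tb$flag_s2 == "ok"
  if ("flag_s3" %in% names(tb)) ok3 <- ok3 & tb$flag_s3 == "ok"
  mask <- is.finite(tb$erp_s2) & tb$erp_s2 <= ceiling_ms
  rows1 <- ok2 & (if (mask_s2_fit) mask else TRUE)
  rows2 <- ok3 & mask
  if (sum(rows2) < 20) {
    stop("fewer than 20 usable rows after masking (", sum(rows2), ")")
  }
  ranges <- list(tau_out = range(tb$tau_out[rows1 | rows2]),
                 apd_max = range(tb$apd_max[rows1 | rows2]))
  for (nm in names(ranges)) {
    if (diff(ranges[[nm]]) <= 0) {
      stop("rank-deficient cubic design: training input ", nm,
           " has zero spread")
    }
  }
  fit_one <- function(rows, yname) {
    x <- standardize(tb$tau_out[rows], ranges$tau_out)
    y <- standardize(tb$apd_max[rows], ranges$apd_max)
    X <- cubic_monomials(x, y)
    qr_X <- qr(X)
    if (qr_X$rank < ncol(X)) {
      stop("rank-deficient cubic design for ", yname,
           ": rank ", qr_X$rank, " < 10; spread the training design")
    }
    cf <- qr.coef(qr_X, tb[[yname]][rows])
    resid <- tb[[yname]][rows] - X %*% cf
    list(coef = drop(cf), ranges = ranges,
         rms = sqrt(mean(resid^2)), n = sum(rows))
  }
  structure(list(f1 = fit_one(rows1, "erp_s2"),
                 f2 = fit_one(rows2, "erp_s3"),
                 ceiling_ms = ceiling_ms,
                 n_dropped_flags = sum(!(ok2 & is.finite(tb$erp_s3)) &
                                         is.finite(tb$erp_s2)),
                 mask_s2_fit = mask_s2_fit),
            class = "erp_surrogates")
}

#' Predict ERP from a surrogate function
#'
#' Polynomial evaluation with flags rather than errors, so samplers can
#' traverse the masked region: attribute `"masked"` marks points whose
#' predicted ERP_S2 exceeds the ceiling (meaningful for `which = "f2"`),
#' and attribute `"extrapolated"` marks inputs outside the training
#' rectangle.
#'
#' @param surr An `erp_surrogates` object.
#' @param tau_out,apd_max Inputs (vectors, ms).
#' @param which `"f1"` (ERP_S2) or `"f2"` (ERP_S3).
#' @param warn_extrapolation Emit a warning when extrapolating.
#' @return Numeric vector of ERP predictions (ms) with logical
#'   attributes `"masked"` and `"extrapolated"`.
#' @export
predict_erp <- function(surr, tau_out, apd_max, which = c("f1", "f2"),
                        warn_extrapolation = FALSE) {
  which <- match.arg(which)
  f <- surr[[which]]
  x <- standardize(tau_out, f$ranges$tau_out)
  y <- standardize(apd_max, f$ranges$apd_max)
  pred <- drop(cubic_monomials(x, y) %*% f$coef)
  extra <- abs(x) > 1 | abs(y) > 1
  if (warn_extrapolation && any(extra)) {
    warning(sum(extra), " prediction(s) outside the training rectangle")
  }
  s2 <- if (which == "f1") pred else {
    x1 <- standardize(tau_out, surr$f1$ranges$tau_out)
    y1 <- standardize(apd_max, surr$f1$ranges$apd_max)
    drop(cubic_monomials(x1, y1) %*% surr$f1$coef)
  }
  attr(pred, "masked") <- s2 > surr$ceiling_ms
  attr(pred, "extrapolated") <- extra
  pred
}

# Value and partial derivatives wrt (tau_out, apd_max); used by the
# analytic posterior gradient.
predict_erp_grad <- function(surr, tau_out, apd_max, which = "f1") {
  f <- surr[[which]]
  rx <- f$ranges$tau_out; ry <- f$ranges$apd_max
  x <- standardize(tau_out, rx)
  y <- standardize(apd_max, ry)
  val <- drop(cubic_monomials(x, y) %*% f$coef)
  dx <- drop(cubic_monomials_dx(x, y) %*% f$coef) * 2 / (rx[2] - rx[1])
  dy <- drop(cubic_monomials_dy(x, y) %*% f$coef) * 2 / (ry[2] - ry[1])
  list(value = val, d_tau_out = dx, d_apd_max = dy)
}

#' GAM-based variance sensitivity indices
#'
#' For each (input, output) pair, fits a univariate penalized-spline GAM
#' (10 basis functions, GCV smoothing) of the output on that input alone
#' and reports `Var(fitted) / Var(output)` as the sensitivity index.
#'
#' @param X Data frame or matrix of inputs (design points).
#' @param Y Data frame, matrix or vector of outputs.
#' @param n_splines Spline basis dimension (default 10).
#' @return Object of class `sensitivity_report`: matrix of indices
#'   (inputs x outputs), entries in `[0, 1]` up to fitting noise; `NA`
#'   where the output variance is zero.
#' @export
gam_sensitivity <- function(X, Y, n_splines = 10) {
  X <- as.data.frame(X)
  Y <- as.data.frame(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  idx <- matrix(NA_real_, ncol(X), ncol(Y),
                dimnames = list(names(X), names(Y)))
  for (j in seq_len(ncol(Y))) {
    y <- Y[[j]]
    keep <- is.finite(y)
    vy <- stats::var(y[keep])
    if (!is.finite(vy) || vy <= 0) next
    for (i in seq_len(ncol(X))) {
      df <- data.frame(y = y[keep], x = X[[i]][keep])
      fit <- mgcv::gam(y ~ s(x, k = n_splines), data = df)
      idx[i, j] <- stats::var(stats::fitted(fit)) / vy
    }
  }
  structure(list(indices = idx, n_splines = n_splines),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("GAM variance sensitivity indices (", x$n_splines, " splines):\n",
      sep = "")
  print(round(x$indices, 3))
  invisible(x)
}

#' Write fitted surrogates to JSON
#'
#' Stores coefficients, standardization constants, residual RMS and the
#' mask rule; round-trips through [read_surrogates()].
#'
#' @param surr An `erp_surrogates` object.
#' @param path Output JSON path.
#' @export
write_surrogates <- function(surr, path) {
  jsonlite::write_json(
    list(f1 = surr$f1, f2 = surr$f2, ceiling_ms = surr$ceiling_ms,
         mask_s2_fit = surr$mask_s2_fit),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fitted surrogates from JSON
#'
#' @param path JSON path written by [write_surrogates()].
#' @return An `erp_surrogates` object.
#' @export
read_surrogates <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("f1", "f2")) {
    x[[nm]]$coef <- as.numeric(x[[nm]]$coef)
    x[[nm]]$ranges <- lapply(x[[nm]]$ranges, as.numeric)
  }
  structure(list(f1 = x$f1, f2 = x$f2, ceiling_ms = x$ceiling_ms,
                 mask_s2_fit = isTRUE(x$mask_s2_fit)),
            class = "erp_surrogates")
}
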