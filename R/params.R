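# Parameterizations of the modified Mitchell-Schaeffer (mMS) model.
#
# Native parameters: (tau_in, tau_out, tau_open, tau_close, D, V_gate).
# Transformed parameters: (cv_max, tau_in, tau_out, tau_open, apd_max),
# chosen so that convex combinations of valid parameter sets remain valid,
# which makes spatial interpolation of parameter fields safe.
#
# Forward maps (with V_gate fixed at 0.1 unless overridden):
#   cv_max  = 0.5 (1 - 2 V_gate) sqrt(2 D / tau_in)        [mm/ms == m/s]
#   apd_max = tau_close log(1 + tau_out (1 - V_gate)^2 / (4 tau_in))

#' Valid ranges of the transformed mMS parameters
#'
#' Physiological ranges in which the transformed parameterization is
#' considered valid: `cv_max` 0.1--1.5 m/s, `tau_in` 0.01--0.30 ms,
#' `tau_out` 1--30 ms, `tau_open` 65--215 ms, `apd_max` 120--270 ms.
#'
#' @return Named list of `c(lo, hi)` ranges.
#' @export
ep_param_ranges <- function() {
  list(
    cv_max   = c(0.1, 1.5),
    tau_in   = c(0.01, 0.30),
    tau_out  = c(1, 30),
    tau_open = c(65, 215),
    apd_max  = c(120, 270)
  )
}

#' Construct a transformed mMS parameter set
#'
#' @param cv_max Maximum conduction velocity (m/s; numerically identical in
#'   mm/ms, the internal unit system).
#' @param tau_in,tau_out,tau_open mMS time constants (ms).
#' @param apd_max Maximum action potential duration (ms).
#' @param check If `TRUE` (default), warn when values fall outside the
#'   physiological ranges of [ep_param_ranges()].  Out-of-range values are
#'   allowed (posterior samples may stray slightly outside the ranges).
#' @return An object of class `ep_params`.
#' @export
ep_params <- function(cv_max, tau_in, tau_out, tau_open, apd_max,
                      check = TRUE) {
  p <- list(cv_max = cv_max, tau_in = tau_in, tau_out = tau_out,
            tau_open = tau_open, apd_max = apd_max)
  vals <- unlist(p)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all transformed parameters must be finite and positive")
  }
  if (isTRUE(check)) {
    rng <- ep_param_ranges()
    for (nm in names(p)) {
      if (p[[nm]] < rng[[nm]][1] || p[[nm]] > rng[[nm]][2]) {
        warning(sprintf("%s = %g outside physiological range [%g, %g]",
                        nm, p[[nm]], rng[[nm]][1], rng[[nm]][2]))
      }
    }
  }
  structure(p, class = "ep_params")
}

#' Construct a native mMS parameter set
#'
#' @param tau_in,tau_out,tau_open,tau_close mMS time constants (ms).
#' @param D Diffusivity (mm^2/ms).
#' @param v_gate Excitation threshold of the normalized voltage
#'   (dimensionless, default 0.1).
#' @return An object of class `mms_params`.
#' @export
mms_params <- function(tau_in, tau_out, tau_open, tau_close, D,
                       v_gate = 0.1) {
  if (any(!is.finite(c(tau_in, tau_out, tau_open, tau_close, D, v_gate)))) {
    stop("all native parameters must be finite")
  }
  if (any(c(tau_in, tau_out, tau_open, tau_close, D) <= 0)) {
    stop("time constants and diffusivity must be positive")
  }
  if (v_gate <= 0 || v_gate >= 0.5) stop("v_gate must lie in (0, 0.5)")
  structure(list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                 tau_close = tau_close, D = D, v_gate = v_gate),
            class = "mms_params")
}

#' Convert transformed parameters to native mMS parameters
#'
#' Inverts the conduction-velocity and APD maps:
#' `D = tau_in * (cv_max / (0.5 (1 - 2 v_gate)))^2 / 2` and
#' `tau_close = apd_max / log(1 + tau_out (1 - v_gate)^2 / (4 tau_in))`.
#'
#' @param p An `ep_params` object.
#' @param v_gate Excitation threshold (default 0.1).
#' @return An `mms_params` object.
#' @export
to_native <- function(p, v_gate = 0.1) {
  stopifnot(inherits(p, "ep_params"))
  D <- p$tau_in * (p$cv_max / (0.5 * (1 - 2 * v_gate)))^2 / 2
  denom <- log(1 + p$tau_out * (1 - v_gate)^2 / (4 * p$tau_in))
  if (!is.finite(denom) || denom <= 0) {
    stop("invalid parameter combination: APD_max map not invertible")
  }
  mms_params(tau_in = p$tau_in, tau_out = p$tau_out, tau_open = p$tau_open,
             tau_close = p$apd_max / denom, D = D, v_gate = v_gate)
}

#' Convert native mMS parameters to transformed parameters
#'
#' @param p An `mms_params` object.
#' @param check Passed to [ep_params()].
#' @return An `ep_params` object.
#' @export
to_transformed <- function(p, check = FALSE) {
  stopifnot(inherits(p, "mms_params"))
  cv <- 0.5 * (1 - 2 * p$v_gate) * sqrt(2 * p$D / p$tau_in)
  apd <- p$tau_close * log(1 + p$tau_out * (1 - p$v_gate)^2 / (4 * p$tau_in))
  ep_params(cv_max = cv, tau_in = p$tau_in, tau_out = p$tau_out,
            tau_open = p$tau_open, apd_max = apd, check = check)
}

#' @export
print.ep_params <- function(x, ...) {
  cat("Transformed mMS parameters:\n")
  cat(sprintf("  cv_max   %8.4f m/s\n  tau_in   %8.4f ms\n", x$cv_max, x$tau_in))
  cat(sprintf("  tau_out  %8.3f ms\n  tau_open %8.2f ms\n  apd_max  %8.2f ms\n",
              x$tau_out, x$tau_open, x$apd_max))
  invisible(x)
}

#' @export
print.mms_params <- function(x, ...) {
  cat("Native mMS parameters:\n")
  cat(sprintf("  tau_in %g  tau_out %g  tau_open %g  tau_close %g ms\n",
              x$tau_in, x$tau_out, x$tau_open, x$tau_close))
  cat(sprintf("  D %g mm^2/ms  v_gate %g\n", x$D, x$v_gate))
  invisible(x)
}
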