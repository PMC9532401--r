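# Locating the discontinuity of the ERP_S3 response surface.
#
# Under S1 600 ms / S2 300 ms pacing, the S1S2S3 response changes regime
# as ERP_S2 grows: ERP_S3 first decreases along a path of increasing
# ERP_S2, then turns sharply upward (a fold in the response surface with
# a near-vertical rise), and finally the S2 beat itself fails to capture
# once ERP_S2 exceeds the S2 interval.  The fold is the feature that
# breaks cubic-surrogate fitting and motivates the 280 ms training
# ceiling; its location is reported as the ERP_S2 level at the ERP_S3
# minimum along the path.

#' Locate the ERP_S3 discontinuity of the strip simulator
#'
#' Sweeps `apd_max` at fixed `tau_out` (with `tau_in` = 0.05 ms,
#' `tau_open` = 120 ms), computing refined ERP_S2 and ERP_S3 at each
#' point, and returns the ERP_S2 level at which the ERP_S3 response
#' turns discontinuously (the fold: trend reversal from decreasing to
#' sharply increasing, or, failing that, the last point before ERP_S3
#' becomes undefined).
#'
#' @param tau_out Fixed tau_out for the path (ms, default 10).
#' @param cv_max Fixed conduction velocity (default 0.6 m/s).
#' @param apd_range `apd_max` sweep range (ms); the default covers
#'   ERP_S2 from about 265 ms to past the fold.
#' @param apd_step Sweep step (ms, default 2).
#' @param proto_s2,proto_s3 Pacing protocols (S1 600 ms, S2 300 ms).
#' @param cfg A [cable_config()].
#' @param refine_ms ERP bisection tolerance (default 0.5).
#' @return List with `erp_s2_at_jump` (ms), the sweep `table`, and the
#'   detection `mode` (`"fold"` or `"failure"`).
#' @export
find_erp_s3_discontinuity <- function(tau_out = 10, cv_max = 0.6,
                                      apd_range = c(215, 252),
                                      apd_step = 2,
                                      proto_s2 = pacing_protocol("S1S2"),
                                      proto_s3 = pacing_protocol("S1S2S3"),
                                      cfg = cable_config(),
                                      refine_ms = 0.5) {
  apds <- seq(apd_range[1], apd_range[2], by = apd_step)
  erp2 <- erp3 <- rep(NA_real_, length(apds))
  for (i in seq_along(apds)) {
    p <- ep_params(cv_max, 0.05, tau_out, 120, apds[i], check = FALSE)
    np <- to_native(p)
    state <- cable_s1_state(np, proto_s2, cfg)
    r2 <- erp_scan(np, state, proto_s2, cfg, refine_ms)
    erp2[i] <- r2$erp
    r3 <- tryCatch({
      if (!test_beat_captures(np, state, proto_s2, cfg, proto_s3$s2)) {
        stop("s2 failure")
      }
      erp_scan(np, state, proto_s3, cfg, refine_ms)
    }, error = function(e) list(erp = NA_real_))
    erp3[i] <- r3$erp
  }
  tb <- data.frame(apd_max = apds, erp_s2 = erp2, erp_s3 = erp3)
  ok <- which(is.finite(erp3))
  if (length(ok) < 3) stop("sweep does not cover the continuous branch")
  d3 <- diff(erp3[ok])
  turn <- which(d3[-length(d3)] < 0 & d3[-1] > 0)
  if (length(turn)) {
    j <- ok[turn[1] + 1] # the minimum point of the fold
    return(list(erp_s2_at_jump = erp2[j], table = tb, mode = "fold"))
  }
  # no interior fold: report the last point with a defined ERP_S3
  j <- ok[length(ok)]
  list(erp_s2_at_jump = erp2[j], table = tb, mode = "failure")
}
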