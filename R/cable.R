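# 1D strip-of-tissue simulator for the mMS monodomain model, used as a
# cheap stand-in for full atrial simulation when measuring ERP under
# extra-stimulus pacing protocols.

#' Cable simulation configuration
#'
#' Geometry and numerics for the strip simulator.  Defaults follow the
#' atrial-simulation settings as closely as possible: 0.3 mm spacing,
#' 0.1 ms diffusion step, 0.02 ms ionic step.  The strip is paced from one
#' end (first `stim_extent` mm of tissue) and activation is measured at
#' `measure_frac` of the cable length.
#'
#' @param length Cable length in mm (default 20).
#' @param dx Node spacing in mm (default 0.3).
#' @param dt_diffusion Diffusion (PDE) time step in ms (default 0.1).
#' @param dt_ionic Ionic (reaction) time step in ms (default 0.02); must
#'   divide `dt_diffusion`.
#' @param stim_extent Length of the stimulated end segment in mm (default
#'   0.9, i.e. 3 nodes at the default spacing).
#' @param measure_frac Measurement site as a fraction of cable length,
#'   strictly inside the cable (default 0.5).
#' @param stim_amp Stimulus current amplitude in 1/ms of normalized
#'   voltage (default 1).
#' @param stim_dur Stimulus duration in ms (default 2).
#' @param capture_window Window after a test stimulus within which an
#'   upward crossing of `act_level` at the measurement site counts as
#'   successful activation (ms, default 300; long enough for the slowest
#'   admissible conduction velocity of 0.1 m/s to reach the strip centre).
#' @param act_level Activation threshold on the upstroke (default 0.7).
#' @return An object of class `cable_config`.
#' @export
cable_config <- function(length = 20, dx = 0.3, dt_diffusion = 0.1,
                         dt_ionic = 0.02, stim_extent = 0.9,
                         measure_frac = 0.5, stim_amp = 1, stim_dur = 2,
                         capture_window = 300, act_level = 0.7) {
  stopifnot(length > 0, dx > 0, dt_diffusion > 0, dt_ionic > 0)
  nsub <- dt_diffusion / dt_ionic
  if (abs(nsub - round(nsub)) > 1e-9) {
    stop("dt_ionic must divide dt_diffusion")
  }
  if (measure_frac <= 0 || measure_frac >= 1) {
    stop("measurement site must be strictly inside the cable")
  }
  n_nodes <- floor(length / dx) + 1
  cfg <- list(length = length, dx = dx, dt_diffusion = dt_diffusion,
              dt_ionic = dt_ionic, stim_extent = stim_extent,
              measure_frac = measure_frac, stim_amp = stim_amp,
              stim_dur = stim_dur, capture_window = capture_window,
              act_level = act_level, n_nodes = n_nodes,
              stim_nodes = max(1, round(stim_extent / dx)),
              measure_node = max(2, min(n_nodes - 1,
                                        round(measure_frac * (n_nodes - 1)) + 1)))
  structure(cfg, class = "cable_config")
}

#' Pacing protocol description
#'
#' @param kind `"S1S2"` or `"S1S2S3"`.
#' @param s1 S1 pacing interval in ms (default 600).
#' @param n_s1 Number of S1 beats (default 8).
#' @param s2 Fixed S2 interval in ms for the S1S2S3 protocol (default 300;
#'   ignored for S1S2).
#' @param resolution Scan resolution of the extra-stimulus interval in ms
#'   (default 10).
#' @param scan_from Upper end of the scanned interval grid in ms (default
#'   400 for S1S2, `s2` for S1S2S3).
#' @param scan_to Lower end of the scanned interval grid in ms (default 120).
#' @return An object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(kind = c("S1S2", "S1S2S3"), s1 = 600, n_s1 = 8,
                            s2 = 300, resolution = 10,
                            scan_from = NULL, scan_to = 120) {
  kind <- match.arg(kind)
  stopifnot(s1 > 0, n_s1 >= 1, resolution > 0)
  if (is.null(scan_from)) scan_from <- if (kind == "S1S2") 400 else s2
  if (kind == "S1S2S3" && !(s1 > s2)) stop("require s1 > s2")
  if (scan_from <= scan_to) stop("scan_from must exceed scan_to")
  structure(list(kind = kind, s1 = s1, n_s1 = n_s1, s2 = s2,
                 resolution = resolution, scan_from = scan_from,
                 scan_to = scan_to),
            class = "pacing_protocol")
}

stim_row <- function(t_on, cfg) {
  c(t_on, cfg$stim_dur, 1, cfg$stim_nodes, cfg$stim_amp)
}

#' Simulate the mMS cable
#'
#' Runs the 1D monodomain mMS model with operator splitting
#' (forward-Euler reaction sub-cycled at `dt_ionic`, Crank-Nicolson
#' diffusion at `dt_diffusion`) and no-flux boundaries.
#'
#' @param p An `mms_params` object (use [to_native()] to convert
#'   transformed parameters).
#' @param stim_times Numeric vector of stimulus onset times (ms), applied
#'   to the stimulated end segment.
#' @param t_total Total simulated time (ms).
#' @param cfg A [cable_config()].
#' @param record `"site"` (measurement-node trace, default) or `"all"`
#'   (full space-time voltage matrix).
#' @param state Optional list with elements `V`, `h` giving the initial
#'   state (default: rest, `V = 0`, `h = 1`).
#' @return List with `times`, `trace` (or `full`), and final `V`, `h`.
#' @export
simulate_cable <- function(p, stim_times, t_total, cfg = cable_config(),
                           record = c("site", "all"), state = NULL) {
  stopifnot(inherits(p, "mms_params"), inherits(cfg, "cable_config"))
  record <- match.arg(record)
  if (is.unsorted(stim_times)) stop("stimulus times must be sorted")
  n <- cfg$n_nodes
  V0 <- if (is.null(state)) numeric(n) else state$V
  h0 <- if (is.null(state)) rep(1, n) else state$h
  stim <- if (length(stim_times)) {
    do.call(rbind, lapply(stim_times, stim_row, cfg = cfg))
  } else {
    matrix(numeric(0), ncol = 5)
  }
  out <- .mms_cable_segment(V0, h0, p$tau_in, p$tau_out, p$tau_open,
                            p$tau_close, p$v_gate, p$D, cfg$dx,
                            cfg$dt_diffusion, cfg$dt_ionic, t_total, stim,
                            as.integer(cfg$measure_node), record == "all")
  out$record <- record
  out
}

interp_crossing <- function(t0, t1, v0, v1, level) {
  t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}

#' Measure activation and repolarization times from a voltage trace
#'
#' Activation is the first upward crossing of 0.7; APD20/30/50/90 are the
#' times from activation until the voltage falls to 0.8/0.7/0.5/0.1
#' respectively (20%, 30%, 50% and 90% recovery of the normalized action
#' potential).  Crossing times are linearly interpolated.  A missing
#' repolarization crossing yields `NA` for that level (absent, not zero).
#'
#' @param times Time vector (ms).
#' @param v Voltage trace at the measurement site.
#' @param t_from Only consider activity strictly after this time (ms).
#' @param act_level Upstroke threshold (default 0.7).
#' @return List with `activated` (logical), `lat` (local activation time,
#'   ms) and `apd20`, `apd30`, `apd50`, `apd90` (ms).
#' @export
measure_trace <- function(times, v, t_from = 0, act_level = 0.7) {
  keep <- times >= t_from
  times <- times[keep]; v <- v[keep]
  res <- list(activated = FALSE, lat = NA_real_, apd20 = NA_real_,
              apd30 = NA_real_, apd50 = NA_real_, apd90 = NA_real_)
  if (length(v) < 2) return(res)
  up <- which(v[-length(v)] < act_level & v[-1] >= act_level)
  if (!length(up)) return(res)
  i <- up[1]
  lat <- interp_crossing(times[i], times[i + 1], v[i], v[i + 1], act_level)
  res$activated <- TRUE
  res$lat <- lat
  levels <- c(apd20 = 0.8, apd30 = 0.7, apd50 = 0.5, apd90 = 0.1)
  after <- times > lat
  tv <- times[after]; vv <- v[after]
  for (nm in names(levels)) {
    lv <- levels[[nm]]
    dn <- which(vv[-length(vv)] >= lv & vv[-1] < lv)
    if (length(dn)) {
      j <- dn[1]
      res[[nm]] <- interp_crossing(tv[j], tv[j + 1], vv[j], vv[j + 1], lv) - lat
    }
  }
  res
}

# Run the S1 train once and cache the state just before the final S1
# stimulus; ERP scans restart from this state so the last beat and the
# test stimuli are re-simulated per candidate interval.
cable_s1_state <- function(p, proto, cfg) {
  t_cache <- (proto$n_s1 - 1) * proto$s1
  if (t_cache == 0) {
    return(list(V = numeric(cfg$n_nodes), h = rep(1, cfg$n_nodes)))
  }
  out <- simulate_cable(p, stim_times = seq(0, by = proto$s1,
                                            length.out = proto$n_s1 - 1),
                        t_total = t_cache, cfg = cfg)
  list(V = out$V, h = out$h)
}

# Number of upward act_level crossings at the measurement site in
# (t_from, t_to], starting the segment from `state`.
segment_upcrossings <- function(p, state, stim_times, t_total, t_from, t_to,
                                cfg) {
  out <- simulate_cable(p, stim_times, t_total, cfg = cfg, state = state)
  .count_upcrossings(out$times, out$trace[, 1], cfg$act_level, t_from, t_to)
}

# Does a test beat at coupling interval `ci` (after the final S1 beat,
# and after an optional fixed S2 beat for S1S2S3) capture?
test_beat_captures <- function(p, state, proto, cfg, ci) {
  if (proto$kind == "S1S2") {
    stims <- c(0, ci)
    need <- 2 # S1 arrival + S2 arrival
    t_from <- 0
    t_end <- ci + cfg$capture_window
  } else {
    stims <- c(0, proto$s2, proto$s2 + ci)
    need <- 3
    t_from <- 0
    t_end <- proto$s2 + ci + cfg$capture_window
  }
  n <- segment_upcrossings(p, state, stims, t_end, t_from, t_end, cfg)
  n >= need
}

erp_scan <- function(p, state, proto, cfg, refine_ms) {
  grid <- seq(proto$scan_from, proto$scan_to, by = -proto$resolution)
  status <- NA
  last_capture <- NA_real_
  first_fail <- NA_real_
  for (ci in grid) {
    if (test_beat_captures(p, state, proto, cfg, ci)) {
      last_capture <- ci
    } else {
      first_fail <- ci
      break
    }
  }
  if (is.na(last_capture)) {
    return(list(erp = NA_real_, bracket = c(NA_real_, NA_real_),
                status = "above_scan_range"))
  }
  if (is.na(first_fail)) {
    return(list(erp = NA_real_, bracket = c(NA_real_, NA_real_),
                status = "below_scan_range"))
  }
  bracket <- c(first_fail, last_capture)
  lo <- first_fail; hi <- last_capture
  while (hi - lo > refine_ms) {
    mid <- (lo + hi) / 2
    if (test_beat_captures(p, state, proto, cfg, mid)) hi <- mid else lo <- mid
  }
  list(erp = hi, bracket = bracket, status = "ok")
}

#' Measure ERP under an S1S2 pacing protocol
#'
#' Scans the S2 coupling interval downwards from `proto$scan_from` in
#' steps of `proto$resolution` until the S2 beat fails to elicit a
#' propagated activation at the measurement site, then refines the
#' bracket by bisection.
#'
#' @param p An `ep_params` object (transformed parameters).
#' @param proto A [pacing_protocol()] with `kind = "S1S2"`.
#' @param cfg A [cable_config()].
#' @param refine_ms Bisection refinement tolerance in ms (default 1).
#' @param state Optional pre-computed S1-train state from the internal
#'   cache (for repeated scans with identical parameters).
#' @return List with `erp` (continuous estimate, ms), `bracket`
#'   (`c(I, I + resolution)`: the failing and capturing grid intervals)
#'   and `status` (`"ok"`, `"above_scan_range"`, `"below_scan_range"`).
#' @export
erp_s1s2 <- function(p, proto = pacing_protocol("S1S2"),
                     cfg = cable_config(), refine_ms = 1, state = NULL) {
  stopifnot(proto$kind == "S1S2")
  np <- to_native(p)
  if (is.null(state)) state <- cable_s1_state(np, proto, cfg)
  erp_scan(np, state, proto, cfg, refine_ms)
}

#' Measure ERP under an S1S2S3 pacing protocol
#'
#' After the S1 train, a fixed premature S2 beat (default 300 ms) is
#' delivered, and the S3 coupling interval is scanned downwards.  The S2
#' beat must itself capture; otherwise the protocol is invalid for these
#' parameters (the regime responsible for the discontinuity of the ERP_S3
#' response surface).
#'
#' @inheritParams erp_s1s2
#' @param proto A [pacing_protocol()] with `kind = "S1S2S3"`.
#' @return As [erp_s1s2()].
#' @export
erp_s1s2s3 <- function(p, proto = pacing_protocol("S1S2S3"),
                       cfg = cable_config(), refine_ms = 1, state = NULL) {
  stopifnot(proto$kind == "S1S2S3")
  np <- to_native(p)
  if (is.null(state)) state <- cable_s1_state(np, proto, cfg)
  # S2 beat must capture for the protocol to make sense
  s2_proto <- pacing_protocol("S1S2", s1 = proto$s1, n_s1 = proto$n_s1,
                              resolution = proto$resolution,
                              scan_from = proto$s2 + proto$resolution,
                              scan_to = proto$s2 - proto$resolution)
  if (!test_beat_captures(np, state, s2_proto, cfg, proto$s2)) {
    stop("protocol invalid for these parameters: the S2 beat fails to capture")
  }
  erp_scan(np, state, proto, cfg, refine_ms)
}

#' Measure planar conduction speed on the cable
#'
#' Paces a rested cable once and measures wavefront speed between 25% and
#' 75% of the cable length from activation-time differences.
#'
#' @param p An `ep_params` object.
#' @param cfg A [cable_config()].
#' @return Conduction speed in mm/ms (= m/s).
#' @export
measure_cv <- function(p, cfg = cable_config()) {
  np <- to_native(p)
  out <- simulate_cable(np, stim_times = 0, t_total = cfg$length / 0.05 + 50,
                        cfg = cfg, record = "all")
  i1 <- max(2, round(0.25 * (cfg$n_nodes - 1)) + 1)
  i2 <- min(cfg$n_nodes - 1, round(0.75 * (cfg$n_nodes - 1)) + 1)
  lat <- function(i) {
    m <- measure_trace(out$times, out$full[, i], act_level = cfg$act_level)
    if (!m$activated) stop("wave did not reach node ", i)
    m$lat
  }
  (i2 - i1) * cfg$dx / (lat(i2) - lat(i1))
}

#' Generate an ERP training table for the surrogate functions
#'
#' Runs both pacing protocols at each design point and records the
#' refined ERP values.  For surrogate training, `tau_in` is fixed at
#' 0.05 ms and `tau_open` at 120 ms; the design varies
#' (`cv_max`, `tau_out`, `apd_max`).
#'
#' @param design Data frame or matrix with columns `cv_max`, `tau_out`,
#'   `apd_max` (additional columns `tau_in`, `tau_open` override the
#'   fixed defaults).
#' @param proto_s2,proto_s3 Pacing protocols for the two measurements.
#' @param cfg A [cable_config()].
#' @param refine_ms Bisection tolerance passed to the ERP scans (default 1).
#' @param verbose Print progress.
#' @return Data frame with one row per design point: the five transformed
#'   parameters, `erp_s2`, `erp_s3`, and `flag_s2`/`flag_s3` status
#'   strings (failed protocol runs are flagged, not dropped).
#' @export
generate_training_table <- function(design,
                                    proto_s2 = pacing_protocol("S1S2"),
                                    proto_s3 = pacing_protocol("S1S2S3"),
                                    cfg = cable_config(), refine_ms = 1,
                                    verbose = FALSE) {
  design <- as.data.frame(design)
  stopifnot(all(c("cv_max", "tau_out", "apd_max") %in% names(design)))
  tau_in <- if ("tau_in" %in% names(design)) design$tau_in else
    rep(0.05, nrow(design))
  tau_open <- if ("tau_open" %in% names(design)) design$tau_open else
    rep(120, nrow(design))
  n <- nrow(design)
  out <- data.frame(cv_max = design$cv_max, tau_in = tau_in,
                    tau_out = design$tau_out, tau_open = tau_open,
                    apd_max = design$apd_max,
                    erp_s2 = NA_real_, erp_s3 = NA_real_,
                    flag_s2 = NA_character_, flag_s3 = NA_character_)
  for (i in seq_len(n)) {
    p <- ep_params(design$cv_max[i], tau_in[i], design$tau_out[i],
                   tau_open[i], design$apd_max[i], check = FALSE)
    np <- to_native(p)
    state <- cable_s1_state(np, proto_s2, cfg)
    r2 <- erp_scan(np, state, proto_s2, cfg, refine_ms)
    out$erp_s2[i] <- r2$erp
    out$flag_s2[i] <- r2$status
    r3 <- tryCatch({
      if (!test_beat_captures(np, state, proto_s2, cfg, proto_s3$s2)) {
        stop("s2_beat_no_capture")
      }
      erp_scan(np, state, proto_s3, cfg, refine_ms)
    }, error = function(e) {
      list(erp = NA_real_, status = paste0("error: ", conditionMessage(e)))
    })
    out$erp_s3[i] <- r3$erp
    out$flag_s3[i] <- r3$status
    if (verbose && i %% 10 == 0) {
      message(sprintf("training table: %d / %d", i, n))
    }
  }
  out
}
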