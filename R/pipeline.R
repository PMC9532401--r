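# End-to-end workflow plumbing: surrogate training from the strip
# simulator, run configuration, and the pipeline driver with a manifest.

#' Train ERP surrogates from the strip simulator
#'
#' Builds a maximin Latin hypercube over (cv_max, tau_out, apd_max)
#' (tau_in and tau_open fixed at 0.05 ms and 120 ms), runs both pacing
#' protocols at each point, and fits the two cubic surrogates.
#'
#' @param n Design size (default 100).
#' @param seed Integer seed.
#' @param cfg A [cable_config()].
#' @param proto_s2,proto_s3 Pacing protocols.
#' @param refine_ms ERP refinement tolerance (default 1 ms).
#' @param verbose Print progress.
#' @return An `erp_surrogates` object with the training table attached
#'   as attribute `"table"`.
#' @export
build_surrogates <- function(n = 100, seed = 1, cfg = cable_config(),
                             proto_s2 = pacing_protocol("S1S2"),
                             proto_s3 = pacing_protocol("S1S2S3"),
                             refine_ms = 1, verbose = FALSE) {
  rng <- ep_param_ranges()
  design <- latin_hypercube(n, rng[c("cv_max", "tau_out", "apd_max")],
                            seed = seed)
  tb <- generate_training_table(design, proto_s2, proto_s3, cfg,
                                refine_ms = refine_ms, verbose = verbose)
  surr <- fit_surrogates(tb)
  attr(surr, "table") <- tb
  surr
}

#' Pipeline run configuration
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Output directory for artifacts.
#' @param surrogate_n Surrogate training design size.
#' @param mesh_kind,mesh_radius,mesh_subdivisions Fixture mesh settings
#'   (used when no `mesh_path` is given).
#' @param mesh_path Optional path to an OBJ/VTK mesh.
#' @param n_eigen Modes to compute for the basis.
#' @param K Eigenfunctions per field for calibration.
#' @param rho_truth Ground-truth lengthscale (skipped if
#'   `observations_path` given).
#' @param n_obs,resolution Observation design settings.
#' @param observations_path Optional CSV of observations
#'   (vertex, protocol, lower, width); skips the truth stage.
#' @param iterations,chains,thin MCMC settings.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("erpfield_run_"),
                       surrogate_n = 100, surrogates_path = NULL,
                       mesh_kind = "sphere",
                       mesh_radius = 25, mesh_subdivisions = 3,
                       mesh_path = NULL, n_eigen = 256, K = 24,
                       rho_truth = 20, n_obs = 10, resolution = 10,
                       observations_path = NULL, iterations = 1000,
                       chains = 4, thin = 10) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full calibration pipeline
#'
#' Stages: fit surrogates -> eigenbasis -> (generate truth and observe |
#' load observations) -> calibrate -> validate.  Every artifact is
#' written under `config$out_dir` and listed in the returned manifest
#' with an MD5 hash and the seed that produced it; a failure halts with
#' the stage name after persisting completed artifacts.
#'
#' @param config A [run_config()].
#' @return The manifest (list), also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  add_artifact <- function(stage, name, path) {
    manifest$stages[[stage]]$artifacts[[name]] <<-
      list(path = path, md5 = unname(tools::md5sum(path)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  surr <- stage("fit-surrogates", {
    if (!is.null(config$surrogates_path)) {
      s <- read_surrogates(config$surrogates_path)
    } else {
      s <- build_surrogates(config$surrogate_n, seed = config$seed)
      utils::write.csv(attr(s, "table"),
                       file.path(config$out_dir, "training_table.csv"),
                       row.names = FALSE)
      add_artifact("fit-surrogates", "table",
                   file.path(config$out_dir, "training_table.csv"))
    }
    write_surrogates(s, file.path(config$out_dir, "surrogates.json"))
    add_artifact("fit-surrogates", "coefficients",
                 file.path(config$out_dir, "surrogates.json"))
    s
  })

  mesh <- stage("mesh", {
    if (!is.null(config$mesh_path)) read_mesh(config$mesh_path) else
      make_fixture_mesh(config$mesh_kind, radius = config$mesh_radius,
                        subdivisions = config$mesh_subdivisions)
  })
  basis <- stage("eigenbasis", {
    b <- solve_eigenproblem(mesh, min(config$n_eigen, nrow(mesh$vertices)))
    utils::write.csv(data.frame(k = seq_along(b$values), lambda = b$values),
                     file.path(config$out_dir, "eigenvalues.csv"),
                     row.names = FALSE)
    add_artifact("eigenbasis", "eigenvalues",
                 file.path(config$out_dir, "eigenvalues.csv"))
    b
  })

  scenario <- NULL
  obs <- stage("observations", {
    if (!is.null(config$observations_path)) {
      tb <- utils::read.csv(config$observations_path)
      erp_observations(tb$vertex, tb$protocol, tb$lower, tb$width)
    } else {
      scenario <- generate_ground_truth(mesh, basis, surr,
                                         rho = config$rho_truth,
                                         seed = config$seed)
      design <- design_observation_sites(mesh, config$n_obs,
                                         seed = config$seed + 10)
      o <- observe_erp(scenario, design, resolution = config$resolution)
      utils::write.csv(as.data.frame(o),
                       file.path(config$out_dir, "observations.csv"),
                       row.names = FALSE)
      add_artifact("observations", "observations",
                   file.path(config$out_dir, "observations.csv"))
      o
    }
  })

  result <- stage("calibrate", {
    lpg <- make_log_posterior(obs, basis, surr, K = config$K)
    rng <- ep_param_ranges()
    K <- config$K
    init_fn <- function(chain) {
      c(mean(rng$tau_out) + stats::rnorm(1, 0, 2),
        log(3) + stats::rnorm(1, 0, 0.2),
        log(10) + stats::rnorm(1, 0, 0.2), stats::rnorm(K, 0, 0.1),
        mean(rng$apd_max) + stats::rnorm(1, 0, 10),
        log(15) + stats::rnorm(1, 0, 0.2),
        log(10) + stats::rnorm(1, 0, 0.2), stats::rnorm(K, 0, 0.1))
    }
    samples <- run_mcmc(lpg, init_fn, iterations = config$iterations,
                        chains = config$chains, thin = config$thin,
                        seed = config$seed + 20)
    fields <- posterior_fields(samples, basis, K = config$K)
    con <- constrain_fields(fields$theta1, fields$theta2, surr, basis)
    fields$theta1 <- con$theta1
    fields$theta2 <- con$theta2
    fields$map <- cbind(con$theta1[, fields$map_draw],
                        con$theta2[, fields$map_draw])
    erp <- posterior_erp(fields, surr)
    summ <- data.frame(vertex = seq_len(basis$n_vertices),
                       tau_out_mean = fields$mean[, 1],
                       tau_out_sd = fields$sd[, 1],
                       apd_max_mean = fields$mean[, 2],
                       apd_max_sd = fields$sd[, 2],
                       erp_s2_mean = erp$mean[, 1],
                       erp_s2_sd = erp$sd[, 1],
                       erp_s3_mean = erp$mean[, 2],
                       erp_s3_sd = erp$sd[, 2])
    utils::write.csv(summ, file.path(config$out_dir, "posterior_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(samples$draws),
                     file.path(config$out_dir, "posterior_draws.csv"),
                     row.names = FALSE)
    add_artifact("calibrate", "summary",
                 file.path(config$out_dir, "posterior_summary.csv"))
    add_artifact("calibrate", "draws",
                 file.path(config$out_dir, "posterior_draws.csv"))
    manifest$stages$calibrate$diagnostics <-
      list(max_rhat = max(samples$rhat), min_ess = min(samples$ess),
           divergence_frac = samples$divergence_frac)
    list(samples = samples, fields = fields, erp = erp)
  })

  if (!is.null(scenario)) {
    stage("validate", {
      metrics <- validate_scenario(scenario, result$erp)
      manifest$stages$validate$metrics <-
        metrics[c("rmse_s2", "rmse_s3", "rmse", "frac_ise_lt3")]
    })
  }
  manifest$completed <- TRUE
  write_manifest()
  invisible(manifest)
}
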