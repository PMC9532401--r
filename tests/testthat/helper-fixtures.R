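# Shared fixtures, built lazily once per test session.  Everything is
# generated in code (no stored data); the strip-simulator surrogate uses
# a reduced 48-point training design (the production default is 100) to
# keep the suite inside its time budget.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Surrogates trained from the real strip simulator (reduced design).
fx_surrogates <- function() {
  fx("surr", function() build_surrogates(n = 48, seed = 7))
}

# Headline fixture mesh: sphere whose ground-truth lengthscale-to-domain
# and observation-spacing ratios match the headline synthetic experiment.
fx_sphere <- function() {
  fx("sphere", function() {
    make_fixture_mesh("sphere", radius = 12.5, subdivisions = 3)
  })
}

fx_sphere_basis <- function() {
  fx("sphere_basis", function() solve_eigenproblem(fx_sphere(), 256))
}

# Coarse mesh and full-spectrum basis for cheap GP/posterior tests.
fx_coarse <- function() {
  fx("coarse", function() {
    make_fixture_mesh("sphere", radius = 12.5, subdivisions = 2)
  })
}

fx_coarse_basis <- function() {
  fx("coarse_basis", function() {
    solve_eigenproblem(fx_coarse(), nrow(fx_coarse()$vertices))
  })
}

# Analytic stand-in surrogate with known coefficients (monotone in both
# inputs on the standardized square); avoids the simulator entirely.
fx_toy_surrogates <- function(ceiling_ms = 280) {
  ranges <- list(tau_out = c(1, 30), apd_max = c(120, 270))
  f1 <- list(coef = c(220, 25, 35, 0, 5, 0, 0, 0, 0, 0),
             ranges = ranges, rms = 0, n = 0)
  f2 <- list(coef = c(185, 15, 25, 0, 3, 0, 0, 0, 0, 0),
             ranges = ranges, rms = 0, n = 0)
  structure(list(f1 = f1, f2 = f2, ceiling_ms = ceiling_ms,
                 mask_s2_fit = TRUE),
            class = "erp_surrogates")
}

# Grid-triangulated planar unit square (for flat-geometry oracles).
fx_square_mesh <- function(n = 21, scale = 1) {
  g <- expand.grid(x = seq(0, 1, length.out = n),
                   y = seq(0, 1, length.out = n))
  v <- cbind(g$x, g$y, 0) * scale
  idx <- function(i, j) (j - 1) * n + i
  f <- list()
  for (j in seq_len(n - 1)) {
    for (i in seq_len(n - 1)) {
      f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
      f[[length(f) + 1]] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  tri_mesh(v, do.call(rbind, f))
}

# Truncate a basis to its first K modes (internal helper re-export).
sub_basis_for_test <- function(b, K) erpfield:::sub_basis(b, K)

# Default init for calibration MCMC (matches run_synthetic_experiment).
fx_init_fn <- function(K) {
  rng <- ep_param_ranges()
  function(chain) {
    c(mean(rng$tau_out) + stats::rnorm(1, 0, 2),
      log(3) + stats::rnorm(1, 0, 0.2),
      log(10) + stats::rnorm(1, 0, 0.2), stats::rnorm(K, 0, 0.1),
      mean(rng$apd_max) + stats::rnorm(1, 0, 10),
      log(15) + stats::rnorm(1, 0, 0.2),
      log(10) + stats::rnorm(1, 0, 0.2), stats::rnorm(K, 0, 0.1))
  }
}
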