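---
title: "Calibrating atrial EP parameter fields from ERP brackets: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating atrial EP parameter fields from ERP brackets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, the
numerical choices, and what the synthetic experiments do and do not
establish. Nothing below states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The electrophysiology model and its reparameterization

Tissue excitation follows the modified Mitchell–Schaeffer (mMS)
monodomain model: a normalized voltage $V_m$ with diffusion $D$, a cubic
inward current gated by $h$ with threshold $V_{gate} = 0.1$, a linear
outward current with time constant $\tau_{out}$, and a recovery gate $h$
that closes with $\tau_{close}$ above threshold and reopens with
$\tau_{open}$ below it. The package works in the transformed space
$(CV_{max}, \tau_{in}, \tau_{out}, \tau_{open}, APD_{max})$, where

$$CV_{max} = 0.5\,(1 - 2V_{gate})\sqrt{2D/\tau_{in}}, \qquad
  APD_{max} = \tau_{close}\,\log\!\big(1 + \tau_{out}(1-V_{gate})^2/(4\tau_{in})\big).$$

The point of the transformation is closure under convex combination:
spatially interpolating valid parameters yields valid parameters, which
is what makes GP modelling of the fields safe. Valid ranges:
$CV_{max}$ 0.1–1.5 m/s, $\tau_{in}$ 0.01–0.30 ms, $\tau_{out}$ 1–30 ms,
$\tau_{open}$ 65–215 ms, $APD_{max}$ 120–270 ms. Range violations warn
rather than error, because posterior draws may stray slightly outside.

## 2. The strip simulator and its numerics

ERP under a pacing protocol depends only on local tissue properties, so
a 1D strip stands in for the atrium: 20 mm of cable at
$dx = 0.3$ mm, stimulated over the first 0.9 mm (rectangular current,
1/ms for 2 ms), with activation detected at the cable midpoint as an
upward crossing of $V_m = 0.7$ within 300 ms of the test stimulus.
Strip length, stimulus shape/strength and the capture criterion are
package decisions — the source workflow leaves them unspecified — and
are recorded in `cable_config()` defaults. Time integration is operator
splitting: forward-Euler reaction sub-cycled at 0.02 ms inside a
Crank–Nicolson diffusion step of 0.1 ms (unconditionally stable; the
admissible $D$ range violates the explicit stability bound at this
$dx$). Protocols pace 8 S1 beats at 600 ms, then scan the extra
stimulus downward in 10 ms steps; the failing/capturing pair is the ERP
bracket, optionally refined by bisection to 1 ms for surrogate training.

Two numerical facts matter for interpretation:

* **Coarse-grid conduction bias.** At $dx = 0.3$ mm the mMS upstroke
  front (width on the order of $CV \cdot \tau_{in}$-scale, well below a
  millimetre at $\tau_{in} = 0.05$ ms) is under-resolved and waves run
  up to ~18% slower than the closed form; the error shrinks to ~2% by
  $dx \approx 0.04$ mm. The physics acceptance test therefore verifies
  the closed form at a refined discretization ($dx = 0.05$,
  $dt = 0.05/0.01$ ms), while production runs keep the stated coarse
  settings — ERP is bracketed at 10 ms and is far less sensitive to the
  CV bias than CV itself.
* **Which APD the closed form is.** $APD_{max}$ corresponds to
  quasi-static termination of the plateau — the fold of the fast
  subsystem, reached at $V = (1+V_{gate})/2$. Time-above-$V_{gate}$
  overshoots it by roughly $4$–$5\,\tau_{out}$ (the repolarization
  tail). The measured quantity that tracks the formula is APD30 (fall
  to $V_m = 0.7$), within ~3 ms for $\tau_{out} \lesssim 15$ ms and
  degrading as $\tau_{out} \to 30$. The asymptote test uses APD30 on a
  fully rested beat over five representative parameter sets.

### The ERP$_{S3}$ discontinuity

Along any path of increasing ERP$_{S2}$ (S1 600 ms), the S1S2S3
response (S2 fixed at 300 ms) first shortens, then turns sharply: a fold
with a near-vertical rise at ERP$_{S2} \approx 283$–$285$ ms, followed
by outright S2-capture failure once ERP$_{S2}$ exceeds the S2 interval
itself (300 ms, by self-consistency of the capture definition). The
fold is what breaks cubic-surface fitting and motivates discarding
training rows with ERP$_{S2} > 280$ ms; `find_erp_s3_discontinuity()`
locates it as the ERP$_{S3}$ minimum along a fixed-$\tau_{out}$ sweep
(default $\tau_{out} = 10$ ms, a mid-range value; the location moves by
only ~2 ms between $\tau_{out} = 3$ and $10$).

## 3. Surrogate functions and sensitivity

The surrogates $f_1, f_2$ are complete bivariate cubics (10 monomials)
in $(\tau_{out}, APD_{max})$ standardized to $[-1,1]$, least-squares
fit to strip-simulator ERP values from a maximin Latin hypercube over
$(CV_{max}, \tau_{out}, APD_{max})$ with $\tau_{in} = 0.05$ ms and
$\tau_{open} = 120$ ms fixed. $CV_{max}$ is varied for robustness but is
not a surrogate input; its effect on ERP is below the scan resolution
(asserted in the tests). The 280 ms discard is applied to both fits by
default (`mask_s2_fit` exposes the alternative of masking only $f_2$,
since the discontinuity lives in the ERP$_{S3}$ response). Training
residual RMS is stored and sits near 1 ms — an order of magnitude below
the 10 ms observation resolution, so surrogate error is immaterial to
calibration. Predictions outside the training rectangle or inside the
masked region are *flagged, never raised*, so the sampler can traverse
them.

Variance-based sensitivity uses the classic one-smooth-at-a-time GAM
recipe: a penalized spline with 10 basis functions (GCV smoothing — the
smoothing rule is a package choice) per (input, output) pair, index
$= \mathrm{Var}(\hat y)/\mathrm{Var}(y)$. On the training table,
$\tau_{out}$ and $APD_{max}$ dominate both ERP outputs, which is the
justification for calibrating exactly those two fields.

## 4. Reduced-rank Gaussian processes on the mesh

The Laplace–Beltrami operator is discretized with cotangent-weight
linear FEM and a lumped (barycentric) mass matrix; natural (Neumann)
boundary conditions keep the constant mode on meshes with holes. The
generalized eigenproblem reduces to a dense symmetric one via
$M^{-1/2} S M^{-1/2}$; the solver computes the full spectrum with base
`eigen()` — deterministic and exact to solver precision, appropriate for
the few-thousand-vertex meshes this package targets (no sparse
iterative eigensolver is among the package's dependencies; this is the
one infrastructure substitution versus a shift-invert Lanczos).

A field is
$\theta(x) = m + \tfrac{\alpha}{|\Phi_1|}\sum_{k=1}^K \eta_k w_k \phi_k(x)$,
$\eta_k \sim N(0,1)$, with $w_k = \sqrt{S(\sqrt{\lambda_k},\rho)/\sum_j S(\sqrt{\lambda_j},\rho)}$
and $S$ the stationary 2-D spectral density of the chosen kernel
(exponentiated quadratic by default; Matérn-5/2 for ground truths). Two
conventions needed fixing because the source leaves them open:

* **Spectral dimension** $d = 2$: the intrinsic dimension of the
  manifold.
* **Normalization.** Any constant factor on $S$ is absorbed by the
  inferred amplitude, so the package normalizes the weight vector; with
  mass-orthonormal $\phi_k$ (so $|\Phi_1| = 1/\sqrt{\text{area}}$) this
  makes the pointwise prior sd $\approx \alpha$ for any $K$ and $\rho$
  — $\alpha$ is directly interpretable in milliseconds, and the
  Monte-Carlo test checks sd within 10% of $\alpha$.

Lengthscale units are mesh distance units; `calibrate_lengthscale_mm()`
reproduces the empirical mm-per-unit factor by regressing sample
correlations on approximate geodesic distance. Geodesics are Dijkstra
over the mesh edge graph *augmented with two-triangle unfolding
shortcuts* (pure edge-graph distances overestimate flat-geometry
distances by ~12%, which broke the 10% flat-square calibration check;
with shortcuts the bias is ~2–3%).

Biharmonic distance
$d^2_{BH}(i,j) = \sum_{\lambda_k > 0} (\phi_k(i)-\phi_k(j))^2/\lambda_k^2$
supplies cheap topology-respecting weights ($1/d_{BH}^4$) for the
constraint projection. The two-mesh workflow (`transfer_field`) is
optional; everything defaults to a single mesh.

## 5. Interval likelihood, priors, and MCMC

An observation is a bracket $[I, I+\Delta]$ at a vertex for one
protocol. The exact likelihood is a top-hat on the bracket; the package
uses the smooth surrogate: an equal-weight mixture of $N = \Delta$
normals with sd 1 ms centred at $c_i = I + (i - \tfrac12)$. It
integrates to one, is symmetric about the midpoint, is approximately
flat in the interior (variation < 0.2 nats on $[I+2, I+\Delta-2]$,
asserted), and decays smoothly at the edges — a small, known bias
toward the bracket centre, which is the price of infinite support for
gradient-based MCMC. No padding is applied by default.

The posterior over
$\psi = (m_1, m_2, \alpha_1, \alpha_2, \rho_1, \rho_2, \eta_1, \eta_2)$
uses $\rho_l \sim \mathrm{InvGamma}(1.01, 20)$,
$\alpha_l \sim \mathrm{InvGamma}(1, 5)$, $\eta \sim N(0, I)$, and flat
$m_l$ — truncated to the physical range ±50% so the posterior stays
proper even with no data (the sampler never reaches the bound in
practice). Positive parameters are sampled on the log scale with the
Jacobian included. Gradients are fully analytic (the chain runs through
the normalized spectral weights, the basis expansion, the cubic
surrogate partials, and the mixture's softmax derivative) and are
verified against central finite differences to 1e-5.

The sampler is plain HMC: jittered leapfrog length (8–24 steps),
dual-averaged step size targeting 0.8 acceptance, and a diagonal mass
matrix estimated in a warm-up window. Burn-in is the first 50% of each
chain; the pooled remainder is randomly thinned (uniform subsampling
without replacement, seeded) — the default 5000 × 8 configuration
retains exactly 200 draws. Split-$\hat R$, a basic ESS, and the
divergent-transition fraction are always reported; divergences above 2%
warn. The amplitude/coefficient decomposition $(\alpha_l, \eta_l)$ is
only weakly identified, so $\hat R$ on individual hyperparameters can be
large while the *field-space* posteriors (what validation scores) are
stable; diagnostics are reported per coordinate so this is visible.

Posterior draws are mapped to fields on all vertices, then through the
surrogates to ERP; the constraint projection replaces parameters at
vertices with predicted ERP$_{S2} > 280$ ms by biharmonic-weighted
averages of acceptable vertices, iterated to a cap of 10 passes (the
averaged value can itself offend; iteration was a package decision where
the source is silent) and flagging any draw that cannot be repaired.

## 6. What the synthetic experiments emulate — and what they don't

Ground truths are independent Matérn-5/2 draws ($m=0$, $\alpha=1$, 256
modes or all available on small fixtures) min–max scaled into the full
parameter ranges (quantile scaling is available by flag), constrained,
and pushed through the surrogates; observation sites are a maximin
selection among vertices at least 0.6 cm (graph distance) from any
boundary; brackets are the 10 ms grid cells containing the true ERP.

The bundled fixture meshes are a sphere, a cylinder with two boundary
loops, and an ellipsoid with polar holes. The headline recovery test
uses a **12.5 mm sphere**: with the stated truth lengthscale of 20 mesh
units (mm here), the lengthscale-to-domain ratio (~0.5 of the geodesic
diameter) and the 10-site observation-spacing-to-lengthscale ratio
(~0.6) match the full-scale configuration the method was designed for.
This was fixed once from those stated values. A green recovery test
establishes that the whole chain — simulator-trained surrogates,
eigenbasis, interval likelihood, HMC, constraint projection — recovers
smooth fields from 10 brackets at 10 ms resolution on a closed
two-manifold. It does **not** establish performance on real atrial
geometry (pulmonary-vein extrapolation regions, boundary effects),
robustness to model misspecification (truths here are generated by the
same GP family the prior uses, up to the RBF/Matérn mismatch, which is
deliberate), or behaviour under measurement error beyond bracketing.

Validation metrics: RMSE of the MAP ERP fields over all vertices, and
the per-vertex independent standard error
ISE $= |$truth $-$ posterior mean$| /$ posterior sd (vertices with zero
posterior sd are excluded with a count). The sweep harness runs the
lengthscale × observation-count × resolution grid at desk scale
(5 truths × 2 designs per cell on a 162-vertex sphere with short
chains; the full-scale grid is available by argument) and asserts the
qualitative trends — RMSE non-increasing in observation count and in
lengthscale, within one standard deviation — rather than any figure-read
numbers.

## 7. Known limitations

* Dense eigensolver: quadratic memory in vertex count; fine to a few
  thousand vertices, not for a 10^5-vertex clinical mesh (use the
  two-mesh workflow, which exists for exactly this reason).
* Plain HMC with jittered L is not NUTS; mixing on
  $(\alpha_l, \rho_l)$ is adequate but not luxurious at desk scale.
* Graph geodesics (even unfolded) slightly overestimate true
  polyhedral distance; `calibrate_lengthscale_mm` inherits a small
  positive bias.
* The likelihood's edge decay biases inference mildly toward bracket
  interiors; at coarse resolutions and many observations this can
  perturb the RMSE-vs-n trend, which is why the sweep assertion allows
  one standard deviation of slack.
* The strip's stimulus/capture conventions are package decisions; ERP
  levels shift by a few ms under reasonable alternatives, uniformly
  across both protocols.
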