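# Space-filling designs: maximin-optimized Latin hypercubes in parameter
# space and maximin site selection on mesh vertices.

#' Maximin-optimized Latin hypercube design
#'
#' One point per axis stratum per dimension; the design is then improved
#' by random within-column swaps that are kept whenever they increase
#' the minimum pairwise distance in the unit cube (hill climbing with a
#' fixed iteration budget).
#'
#' @param n Number of points (>= 2).
#' @param ranges Named list of `c(lo, hi)` ranges, one per dimension.
#' @param seed Integer seed.
#' @param optimize Run the maximin hill climb (default TRUE).
#' @param iterations Swap budget (default 2000).
#' @return Data frame with one column per range, `n` rows.
#' @export
latin_hypercube <- function(n, ranges, seed = 1, optimize = TRUE,
                            iterations = 2000) {
  stopifnot(n >= 2, length(ranges) >= 1)
  d <- length(ranges)
  withr::with_seed(seed, {
    # u[i, j] in (0,1): stratified per column
    u <- vapply(seq_len(d), function(j) {
      (sample.int(n) - stats::runif(n)) / n
    }, numeric(n))
    if (optimize && d >= 2) {
      mindist2 <- function(m) min(stats::dist(m))
      best <- mindist2(u)
      for (it in seq_len(iterations)) {
        j <- sample.int(d, 1)
        ij <- sample.int(n, 2)
        cand <- u
        cand[ij, j] <- cand[rev(ij), j]
        cd <- mindist2(cand)
        if (cd > best) {
          u <- cand
          best <- cd
        }
      }
    }
    out <- as.data.frame(vapply(seq_len(d), function(j) {
      r <- ranges[[j]]
      r[1] + u[, j] * (r[2] - r[1])
    }, numeric(n)))
    names(out) <- names(ranges)
    out
  })
}

#' Select ERP measurement sites on a mesh (maximin design)
#'
#' Chooses `n` vertices maximizing the minimum pairwise geodesic
#' (edge-graph) distance, among vertices at least `exclusion_mm` from
#' any boundary vertex.  Greedy farthest-point seeding followed by
#' exchange improvement.
#'
#' @param mesh A `tri_mesh`.
#' @param n Number of sites.
#' @param exclusion_mm Boundary exclusion radius in mm (default 6, i.e.
#'   0.6 cm).
#' @param seed Integer seed.
#' @param iterations Exchange budget (default 200).
#' @return Object of class `obs_design`: list with `vertices` (indices),
#'   `min_dist` (mm), `admissible` (candidate set).
#' @export
design_observation_sites <- function(mesh, n, exclusion_mm = 6, seed = 1,
                                     iterations = 200) {
  nv <- nrow(mesh$vertices)
  adm <- seq_len(nv)
  if (length(mesh$boundary_vertices)) {
    bd <- mesh_geodesics(mesh, from = mesh$boundary_vertices)
    dmin <- apply(bd, 2, min)
    adm <- which(dmin >= exclusion_mm)
  }
  if (length(adm) < n) {
    stop("only ", length(adm), " admissible vertices for n = ", n)
  }
  gd <- mesh_geodesics(mesh, from = adm, to = adm)
  crit <- function(sel) min(gd[sel, sel][upper.tri(diag(length(sel)))])
  withr::with_seed(seed, {
    sel <- sample.int(length(adm), 1)
    while (length(sel) < n) {
      dmin <- apply(gd[sel, , drop = FALSE], 2, min)
      sel <- c(sel, which.max(dmin))
    }
    best <- crit(sel)
    for (it in seq_len(iterations)) {
      i <- sample(seq_len(n), 1)
      cand <- sel
      cand[i] <- sample(setdiff(seq_along(adm), sel), 1)
      cb <- crit(cand)
      if (cb > best) {
        sel <- cand
        best <- cb
      }
    }
    structure(list(vertices = adm[sel], min_dist = best, admissible = adm),
              class = "obs_design")
  })
}
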