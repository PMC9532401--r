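# Triangle surface meshes: construction, validation, fixtures, and
# plain-text I/O.  A mesh is a list with `vertices` (n x 3, mm) and
# `faces` (m x 3, 1-based vertex indices).

#' Construct a triangle mesh
#'
#' @param vertices Numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces Integer matrix, m x 3, 1-based vertex indices.
#' @param validate Check manifoldness and triangle quality (default TRUE).
#' @return Object of class `tri_mesh` with components `vertices`, `faces`,
#'   `boundary_vertices` (indices of vertices on boundary edges).
#' @export
tri_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  n <- nrow(vertices)
  if (min(faces) < 1 || max(faces) > n) stop("face indices out of range")
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(key)
  if (validate) {
    if (any(cnt > 2)) {
      bad <- names(cnt)[which(cnt > 2)[1]]
      stop("non-manifold mesh: edge (", bad, ") shared by more than 2 triangles")
    }
    a <- triangle_areas(vertices, faces)
    if (any(a <= 1e-14)) {
      stop("degenerate (zero-area) triangle at face ",
           which(a <= 1e-14)[1])
    }
  }
  bkey <- names(cnt)[cnt == 1]
  bv <- if (length(bkey)) {
    sort(unique(as.integer(unlist(strsplit(bkey, " ")))))
  } else {
    integer(0)
  }
  structure(list(vertices = vertices, faces = faces,
                 boundary_vertices = bv),
            class = "tri_mesh")
}

triangle_areas <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - v1
  e2 <- vertices[faces[, 3], , drop = FALSE] - v1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh
#' @param mesh A `tri_mesh`.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh$vertices, mesh$faces))

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces, %d boundary vertices, area %.2f\n",
              nrow(x$vertices), nrow(x$faces), length(x$boundary_vertices),
              mesh_area(x)))
  invisible(x)
}

#' Edge graph of a mesh (igraph, edge lengths as weights)
#'
#' In addition to mesh edges, every pair of triangles sharing an edge
#' contributes a shortcut between their opposite vertices, weighted by
#' the straight-line distance in the planar unfolding of the two
#' triangles.  This keeps Dijkstra distances close to true polyhedral
#' geodesics (the pure edge graph overestimates by the lattice metric).
#'
#' @param mesh A `tri_mesh`.
#' @return An igraph graph with `weight` edge attribute in mm.
#' @keywords internal
mesh_edge_graph <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  opp <- c(f[, 3], f[, 1], f[, 2])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  first <- match(key, key)
  dup <- which(first != seq_along(key)) # second triangle of each edge
  ex <- list()
  if (length(dup)) {
    i <- e[dup, 1]; j <- e[dup, 2]
    a <- opp[first[dup]]; b <- opp[dup]
    ed <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    len <- sqrt(rowSums(ed^2))
    eh <- ed / len
    loc <- function(p) {
      d <- p - v[i, , drop = FALSE]
      t <- rowSums(d * eh)
      h2 <- pmax(rowSums(d^2) - t^2, 0)
      cbind(t, sqrt(h2))
    }
    la <- loc(v[a, , drop = FALSE])
    lb <- loc(v[b, , drop = FALSE])
    w_unfold <- sqrt((la[, 1] - lb[, 1])^2 + (la[, 2] + lb[, 2])^2)
    ex <- list(cbind(a, b, w_unfold))
  }
  base_w <- sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                          v[e[, 2], , drop = FALSE])^2))
  all_e <- rbind(cbind(e, base_w), do.call(rbind, ex))
  pair <- cbind(pmin(all_e[, 1], all_e[, 2]), pmax(all_e[, 1], all_e[, 2]))
  keep <- !duplicated(paste(pair[, 1], pair[, 2]))
  g <- igraph::graph_from_edgelist(matrix(as.integer(pair[keep, ]),
                                          ncol = 2), directed = FALSE)
  igraph::E(g)$weight <- all_e[keep, 3]
  g
}

#' Approximate geodesic distances along mesh edges
#'
#' Dijkstra shortest paths over the edge graph; a small overestimate of
#' the true polyhedral geodesic distance.
#'
#' @param mesh A `tri_mesh`.
#' @param from,to Vertex index vectors (default: all vertices).
#' @return Distance matrix in mm.
#' @export
mesh_geodesics <- function(mesh, from = NULL, to = NULL) {
  g <- mesh_edge_graph(mesh)
  n <- nrow(mesh$vertices)
  if (is.null(from)) from <- seq_len(n)
  if (is.null(to)) to <- seq_len(n)
  igraph::distances(g, v = from, to = to, algorithm = "dijkstra")
}

# ---------------------------------------------------------------------------
# Fixture meshes

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v / sqrt(1 + t^2), faces = f)
}

subdivide_once <- function(v, f) {
  env <- new.env(hash = TRUE)
  nv <- nrow(v)
  newv <- list()
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    id <- env[[key]]
    if (!is.null(id)) return(id)
    nv <<- nv + 1
    newv[[length(newv) + 1]] <<- (v[i, ] + v[j, ]) / 2
    env[[key]] <- nv
    nv
  }
  nf <- matrix(0L, nrow(f) * 4, 3)
  for (k in seq_len(nrow(f))) {
    a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
    nf[(4 * k - 3):(4 * k), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(cc, ca, bc), c(ab, bc, ca))
  }
  list(vertices = rbind(v, do.call(rbind, newv)), faces = nf)
}

#' Generate a fixture mesh
#'
#' Deterministic synthetic test meshes (stand-ins for a patient atrial
#' mesh): `"sphere"` (closed; eigen-spectrum oracle), and
#' `"cylinder-with-holes"` / `"ellipsoid-with-holes"` (open; boundary
#' loops exercise boundary-exclusion rules).
#'
#' @param kind One of `"sphere"`, `"cylinder-with-holes"`,
#'   `"ellipsoid-with-holes"`.
#' @param radius Sphere/ellipsoid base radius in mm (default 1).
#' @param subdivisions Icosphere subdivision level (default 3: 642
#'   vertices).
#' @param axes Ellipsoid semi-axis multipliers (length 3).
#' @param cap_angle Polar angle (radians) of the removed caps for
#'   `"ellipsoid-with-holes"` (default 0.45).
#' @param n_theta,n_len Circumferential/length resolution for the
#'   cylinder; `cyl_length` its length in mm.
#' @param cyl_length Cylinder length (default `3 * radius`).
#' @return A `tri_mesh`.
#' @export
make_fixture_mesh <- function(kind = c("sphere", "cylinder-with-holes",
                                       "ellipsoid-with-holes"),
                              radius = 1, subdivisions = 3,
                              axes = c(1, 0.8, 0.65), cap_angle = 0.45,
                              n_theta = 24, n_len = 24,
                              cyl_length = 3 * radius) {
  kind <- match.arg(kind)
  if (kind == "cylinder-with-holes") {
    th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
    z <- seq(0, cyl_length, length.out = n_len)
    v <- cbind(radius * cos(rep(th, times = n_len)),
               radius * sin(rep(th, times = n_len)),
               rep(z, each = n_theta))
    idx <- function(i, j) (j - 1) * n_theta + ((i - 1) %% n_theta) + 1
    f <- list()
    for (j in seq_len(n_len - 1)) {
      for (i in seq_len(n_theta)) {
        f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
        f[[length(f) + 1]] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
      }
    }
    return(tri_mesh(v, do.call(rbind, f)))
  }
  ico <- icosahedron()
  v <- ico$vertices; f <- ico$faces
  for (s in seq_len(subdivisions)) {
    out <- subdivide_once(v, f)
    v <- out$vertices / sqrt(rowSums(out$vertices^2)) # reproject to sphere
    f <- out$faces
  }
  v <- v * radius
  if (kind == "sphere") return(tri_mesh(v, f))
  # ellipsoid with polar caps removed
  polar <- acos(pmin(1, pmax(-1, v[, 3] / radius)))
  drop_v <- polar < cap_angle | polar > pi - cap_angle
  keep_f <- !apply(matrix(drop_v[f], ncol = 3), 1, any)
  f <- f[keep_f, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v)); remap[used] <- seq_along(used)
  v <- v[used, , drop = FALSE]
  f <- matrix(remap[f], ncol = 3)
  v <- sweep(v, 2, axes, `*`)
  tri_mesh(v, f)
}

# ---------------------------------------------------------------------------
# Plain-text mesh I/O (OBJ and legacy ASCII VTK polydata)

#' Read a triangle mesh from OBJ or legacy ASCII VTK
#'
#' @param path File path; format chosen by extension (`.obj`, `.vtk`).
#' @return A `tri_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
      as.numeric(x[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
    return(tri_mesh(v, f))
  }
  if (ext == "vtk") {
    ip <- grep("^POINTS", lines)
    np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
    nums <- as.numeric(scan(text = paste(lines[(ip + 1):length(lines)],
                                         collapse = " "),
                            what = "", quiet = TRUE, n = 3 * np))
    v <- matrix(nums, ncol = 3, byrow = TRUE)
    ic <- grep("^POLYGONS|^CELLS", lines)[1]
    nc <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
    cn <- scan(text = paste(lines[(ic + 1):length(lines)], collapse = " "),
               quiet = TRUE, n = 4 * nc)
    cn <- matrix(cn, ncol = 4, byrow = TRUE)
    if (any(cn[, 1] != 3)) stop("only triangle cells supported")
    return(tri_mesh(v, cn[, 2:4] + 1L))
  }
  stop("unsupported mesh format: ", ext)
}

#' Write a triangle mesh to OBJ or legacy ASCII VTK
#'
#' @param mesh A `tri_mesh`.
#' @param path Output path; format chosen by extension.
#' @param field Optional per-vertex scalar field written as VTK point data.
#' @export
write_mesh <- function(mesh, path, field = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
    return(invisible(path))
  }
  if (ext == "vtk") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "erpfield mesh", "ASCII",
                 "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(mesh$vertices))), con)
    writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(mesh$faces),
                       4 * nrow(mesh$faces)), con)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
    if (!is.null(field)) {
      writeLines(c(sprintf("POINT_DATA %d", nrow(mesh$vertices)),
                   "SCALARS field float 1", "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", field), con)
    }
    return(invisible(path))
  }
  stop("unsupported mesh format: ", ext)
}
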