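#' Triangular surface mesh
#'
#' The universal currency of the cap-design pipeline: a list with an `n x 3`
#' numeric `vertices` matrix (millimeters) and an `m x 3` integer `faces`
#' matrix of 1-based vertex indices.
#'
#' @param vertices numeric matrix with 3 columns (mm).
#' @param faces integer matrix with 3 columns, 1-based vertex indices.
#' @param validate check index ranges and degenerate faces.
#' @return an object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (length(faces) && ncol(faces) != 3L) stop("faces must have 3 columns")
  if (validate && length(faces)) {
    if (anyNA(faces) || min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("a face repeats a vertex")
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (mesh_is_closed(x)) ", closed" else ""))
  invisible(x)
}

#' Polygonal mesh (faces of arbitrary arity)
#'
#' @param vertices numeric matrix with 3 columns (mm).
#' @param faces list of integer vectors (1-based, length >= 3).
#' @return an object of class `polymesh`.
#' @export
polymesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  faces <- lapply(faces, as.integer)
  if (any(vapply(faces, length, 1L) < 3L)) stop("polygon faces need >= 3 vertices")
  idx <- unlist(faces, use.names = FALSE)
  if (length(idx) && (min(idx) < 1L || max(idx) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "polymesh")
}

#' @export
print.polymesh <- function(x, ...) {
  cat(sprintf("<polymesh> %d vertices, %d faces\n",
              nrow(x$vertices), length(x$faces)))
  invisible(x)
}

# ------------------------------------------------------------------ edges

# directed half-edges as a 2-column matrix (one row per face edge)
half_edges <- function(mesh) {
  f <- mesh$faces
  rbind(f[, c(1, 2), drop = FALSE],
        f[, c(2, 3), drop = FALSE],
        f[, c(3, 1), drop = FALSE])
}

edge_key <- function(e) {
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Unique undirected edges of a mesh
#' @param mesh a [trimesh].
#' @return 2-column integer matrix.
#' @export
mesh_edges <- function(mesh) {
  he <- half_edges(mesh)
  und <- cbind(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  unique(und)
}

# incidence count of each undirected edge (named by key)
edge_incidence <- function(mesh) {
  table(edge_key(half_edges(mesh)))
}

# run-length incidence counts on numeric edge keys (fast path)
edge_incidence_counts <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  a <- c(f[, 1], f[, 2], f[, 3])
  b <- c(f[, 2], f[, 3], f[, 1])
  key <- pmin(a, b) * (nv + 1) + pmax(a, b)
  rle(sort(key))$lengths
}

#' Is every edge shared by exactly two faces?
#' @param mesh a [trimesh].
#' @export
mesh_is_closed <- function(mesh) {
  if (!nrow(mesh$faces)) return(FALSE)
  all(edge_incidence_counts(mesh) == 2L)
}

#' Boundary edges (incident to exactly one face)
#' @param mesh a [trimesh].
#' @return 2-column integer matrix of directed boundary edges.
#' @export
mesh_boundary_edges <- function(mesh) {
  he <- half_edges(mesh)
  nv <- nrow(mesh$vertices)
  key <- pmin(he[, 1], he[, 2]) * (nv + 1) + pmax(he[, 1], he[, 2])
  # an edge is boundary when its undirected key occurs exactly once
  dup_fwd <- duplicated(key)
  dup_bwd <- duplicated(key, fromLast = TRUE)
  he[!(dup_fwd | dup_bwd), , drop = FALSE]
}

#' Ordered boundary loops of an open mesh
#'
#' @param mesh a [trimesh].
#' @return list of integer vectors, each an ordered cycle (or path) of vertex
#'   indices along one boundary loop.
#' @export
mesh_boundary_loops <- function(mesh) {
  be <- mesh_boundary_edges(mesh)
  if (!nrow(be)) return(list())
  loops <- list()
  remaining <- be
  while (nrow(remaining)) {
    start <- remaining[1, 1]
    loop <- c(start)
    cur <- start
    repeat {
      cand <- remaining[remaining[, 1] == cur, , drop = FALSE]
      if (!nrow(cand)) break
      nxtv <- cand[1, 2]
      remaining <- remaining[!(remaining[, 1] == cur & remaining[, 2] == nxtv), ,
                             drop = FALSE]
      if (nxtv == start) break
      loop <- c(loop, nxtv)
      cur <- nxtv
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Euler characteristic V - E + F
#' @param mesh a [trimesh].
#' @export
mesh_euler <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

# ------------------------------------------------------------- geometry

tri_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

cross_rows <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-face areas
#' @param mesh a [trimesh].
#' @export
mesh_face_areas <- function(mesh) {
  tc <- tri_corners(mesh)
  n <- cross_rows(tc$b - tc$a, tc$c - tc$a)
  0.5 * sqrt(rowSums(n^2))
}

#' Total surface area
#' @param mesh a [trimesh].
#' @export
mesh_area <- function(mesh) sum(mesh_face_areas(mesh))

#' Per-face unit normals
#' @param mesh a [trimesh].
#' @export
mesh_face_normals <- function(mesh) {
  tc <- tri_corners(mesh)
  n <- cross_rows(tc$b - tc$a, tc$c - tc$a)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Angle-weighted per-vertex unit normals
#' @param mesh a [trimesh].
#' @export
mesh_vertex_normals <- function(mesh) {
  tc <- tri_corners(mesh)
  fn <- cross_rows(tc$b - tc$a, tc$c - tc$a)
  len <- sqrt(rowSums(fn^2)); len[len == 0] <- 1
  fn <- fn / len
  corner_angle <- function(p, q, r) {
    u <- q - p; v <- r - p
    cu <- sqrt(rowSums(u^2)); cv <- sqrt(rowSums(v^2))
    cu[cu == 0] <- 1; cv[cv == 0] <- 1
    acos(pmin(1, pmax(-1, rowSums(u * v) / (cu * cv))))
  }
  w <- cbind(corner_angle(tc$a, tc$b, tc$c),
             corner_angle(tc$b, tc$c, tc$a),
             corner_angle(tc$c, tc$a, tc$b))
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (corner in 1:3) {
    idx <- mesh$faces[, corner]
    for (d in 1:3)
      vn[, d] <- vn[, d] + tapply_add(idx, w[, corner] * fn[, d], nrow(vn))
  }
  len <- sqrt(rowSums(vn^2)); len[len == 0] <- 1
  vn / len
}

# fast grouped sum into a vector of length n
tapply_add <- function(index, values, n) {
  out <- numeric(n)
  s <- rowsum(values, group = index, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Signed enclosed volume (positive for outward-oriented closed meshes)
#' @param mesh a [trimesh].
#' @export
mesh_volume <- function(mesh) {
  tc <- tri_corners(mesh)
  sum(tc$a[, 1] * (tc$b[, 2] * tc$c[, 3] - tc$b[, 3] * tc$c[, 2]) -
      tc$a[, 2] * (tc$b[, 1] * tc$c[, 3] - tc$b[, 3] * tc$c[, 1]) +
      tc$a[, 3] * (tc$b[, 1] * tc$c[, 2] - tc$b[, 2] * tc$c[, 1])) / 6
}

#' Per-face circumscribed-circle radii
#' @param mesh a [trimesh].
#' @export
mesh_circumradii <- function(mesh) {
  tc <- tri_corners(mesh)
  la <- sqrt(rowSums((tc$b - tc$c)^2))
  lb <- sqrt(rowSums((tc$a - tc$c)^2))
  lc <- sqrt(rowSums((tc$a - tc$b)^2))
  area <- mesh_face_areas(mesh)
  r <- la * lb * lc / (4 * area)
  r[area == 0] <- Inf
  r
}

#' Axis-aligned bounding box
#' @param mesh a [trimesh].
#' @return 2 x 3 matrix (min row, max row).
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min),
        max = apply(mesh$vertices, 2, max))
}

mesh_bbox_diag <- function(mesh) {
  bb <- mesh_bbox(mesh)
  sqrt(sum((bb[2, ] - bb[1, ])^2))
}

#' Apply an affine transform to a mesh
#'
#' @param mesh a [trimesh].
#' @param rotation 3 x 3 matrix applied on the left (may include scaling or
#'   reflection).
#' @param translation length-3 offset added after rotation.
#' @return transformed mesh; face orientation is flipped when the transform
#'   reverses handedness so outward orientation is preserved.
#' @export
mesh_transform <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  f <- mesh$faces
  if (det(rotation) < 0) f <- f[, c(1, 3, 2), drop = FALSE]
  trimesh(v, f, validate = FALSE)
}

#' Drop vertices not referenced by any face
#' @param mesh a [trimesh].
#' @export
mesh_drop_unreferenced <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  trimesh(mesh$vertices[used, , drop = FALSE],
          matrix(map[mesh$faces], ncol = 3), validate = FALSE)
}

#' One round of midpoint (1-to-4) subdivision
#'
#' Splits every triangle into four by inserting edge midpoints; conforming by
#' construction, halves every edge length.
#' @param mesh a [trimesh].
#' @export
mesh_subdivide <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  und <- cbind(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  key <- paste(und[, 1], und[, 2])
  ukey <- unique(key)
  mid_id <- match(key, ukey) + nrow(mesh$vertices)
  first <- !duplicated(key)
  mids <- (mesh$vertices[und[first, 1], , drop = FALSE] +
           mesh$vertices[und[first, 2], , drop = FALSE]) / 2
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2 * nf + seq_len(nf)]
  newf <- rbind(cbind(f[, 1], m12, m31),
                cbind(m12, f[, 2], m23),
                cbind(m31, m23, f[, 3]),
                cbind(m12, m23, m31))
  trimesh(rbind(mesh$vertices, mids), newf, validate = FALSE)
}

#' Taubin lambda/mu smoothing
#'
#' Volume-preserving alternative to plain Laplacian smoothing.
#' @param mesh a [trimesh].
#' @param iterations number of lambda+mu passes.
#' @param lambda positive smoothing factor.
#' @param mu negative inflation factor.
#' @export
mesh_taubin_smooth <- function(mesh, iterations = 10, lambda = 0.5, mu = -0.53) {
  if (iterations <= 0) return(mesh)
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  i <- c(e[, 1], e[, 2])
  j <- c(e[, 2], e[, 1])
  deg <- tabulate(i, nbins = n)
  deg[deg == 0] <- 1
  v <- mesh$vertices
  lap <- function(v) {
    s <- rowsum(v[j, , drop = FALSE], group = i, reorder = TRUE)
    out <- matrix(0, n, 3)
    out[as.integer(rownames(s)), ] <- s
    out / deg - v
  }
  for (it in seq_len(iterations)) {
    v <- v + lambda * lap(v)
    v <- v + mu * lap(v)
  }
  trimesh(v, mesh$faces, validate = FALSE)
}

#' Deterministic surface point sample (area-weighted)
#'
#' Used for sampled Hausdorff distances; deterministic (no RNG): faces are
#' visited in order and receive a number of fixed-pattern barycentric samples
#' proportional to their area.
#' @param mesh a [trimesh].
#' @param n approximate number of points.
#' @export
mesh_sample_points <- function(mesh, n = 2000) {
  areas <- mesh_face_areas(mesh)
  total <- sum(areas)
  per_face <- pmax(1L, as.integer(round(n * areas / total)))
  bary <- function(k) {
    # low-discrepancy-ish fixed pattern
    s <- seq_len(k)
    u <- (s * 0.7548776662466927) %% 1
    v <- (s * 0.5698402909980532) %% 1
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
    cbind(1 - u - v, u, v)
  }
  tc <- tri_corners(mesh)
  idx <- rep.int(seq_along(per_face), per_face)
  b <- do.call(rbind, lapply(per_face, bary))
  tc$a[idx, , drop = FALSE] * b[, 1] +
    tc$b[idx, , drop = FALSE] * b[, 2] +
    tc$c[idx, , drop = FALSE] * b[, 3]
}

#' Sampled symmetric Hausdorff distance between two meshes
#' @param mesh_a,mesh_b [trimesh] objects.
#' @param n sample size per direction.
#' @export
mesh_hausdorff <- function(mesh_a, mesh_b, n = 2000) {
  pa <- mesh_sample_points(mesh_a, n)
  pb <- mesh_sample_points(mesh_b, n)
  da <- cpp_point_mesh_nearest(pa, mesh_b$vertices, mesh_b$faces - 1L)$dist
  db <- cpp_point_mesh_nearest(pb, mesh_a$vertices, mesh_a$faces - 1L)$dist
  max(max(da), max(db))
}

#' Nearest points on a mesh
#'
#' @param points n x 3 matrix of query points.
#' @param mesh a [trimesh].
#' @return list with `points` (projections), `dist`, and `face` (1-based).
#' @export
mesh_nearest_point <- function(points, mesh) {
  points <- rbind(points)
  res <- cpp_point_mesh_nearest(points, mesh$vertices, mesh$faces - 1L)
  res$face <- res$face + 1L
  res
}

#' Cast rays against a mesh
#'
#' @param origins,directions n x 3 matrices.
#' @param mesh a [trimesh].
#' @param tmin,tmax admissible parameter range along each ray.
#' @return list with `t` (nearest-hit parameter or NA), `face` (1-based or 0),
#'   and `n_hits` per ray.
#' @export
mesh_raycast <- function(origins, directions, mesh, tmin = 1e-9, tmax = Inf) {
  origins <- rbind(origins)
  directions <- rbind(directions)
  res <- cpp_ray_mesh(origins, directions, mesh$vertices, mesh$faces - 1L,
                      tmin, tmax)
  res$face <- res$face + 1L
  res
}
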