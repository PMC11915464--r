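#' Grommet specification
#'
#' Geometry of the cutter solids stamped through the cap at each landmark.
#' `cutter_depth` defaults to 8x a 2.5 mm wire so the cutter always spans the
#' strut thickness after wireframe extrusion.
#'
#' @param shape `"circle"` or number of polygon sides (>= 3) for a regular
#'   polygon outline.
#' @param radius outline radius (mm); the printed example uses 4 mm.
#' @param cutter_depth cutter length along the surface normal (mm).
#' @param segments circle discretization (cut outline vertex count).
#' @return object of class `grommet_spec`.
#' @export
grommet_spec <- function(shape = "circle", radius = 4, cutter_depth = 20,
                         segments = 24) {
  if (radius <= 0) stop("grommet radius must be positive")
  if (cutter_depth <= 0) stop("cutter_depth must be positive")
  if (!identical(shape, "circle")) {
    shape <- as.integer(shape)
    if (is.na(shape) || shape < 3) stop("shape must be 'circle' or >= 3 sides")
    segments <- shape
  }
  structure(list(shape = shape, radius = radius, cutter_depth = cutter_depth,
                 segments = as.integer(segments)),
            class = "grommet_spec")
}

#' Cap design parameters
#'
#' @param keep_ratio fraction of head-surface edges kept when coarsening the
#'   cap lattice (the printed examples use 0.05-0.1).
#' @param wire_thickness strut diameter (mm); 2.5-3.5 mm prints well in TPU.
#' @param face_width_fraction face-opening width as a fraction of head width.
#' @param face_height_fraction top of the face opening as a fraction of head
#'   height above the lowest point.
#' @param neck_height_fraction lower rim: bottom fraction of the head height
#'   removed toward the neck.
#' @param ear_cutout cut a relief band above each preauricular point?
#' @param margin_band_width width of the boundary band whose wires are
#'   doubled to protect the cap rim from tearing (mm).
#' @return object of class `cap_params`.
#' @export
cap_params <- function(keep_ratio = 0.05, wire_thickness = 2.5,
                       face_width_fraction = 1 / 3,
                       face_height_fraction = 0.55,
                       neck_height_fraction = 1 / 3,
                       ear_cutout = FALSE, margin_band_width = 10) {
  if (keep_ratio <= 0 || keep_ratio > 1) stop("keep_ratio must be in (0, 1]")
  if (wire_thickness < 1 || wire_thickness > 6)
    stop("wire_thickness outside the printable range (1-6 mm)")
  structure(list(keep_ratio = keep_ratio, wire_thickness = wire_thickness,
                 face_width_fraction = face_width_fraction,
                 face_height_fraction = face_height_fraction,
                 neck_height_fraction = neck_height_fraction,
                 ear_cutout = ear_cutout,
                 margin_band_width = margin_band_width),
            class = "cap_params")
}

#' Canonical head frame from fiducials
#'
#' Origin at the LPA-RPA midpoint; x along the ear axis, y toward the nasion
#' (orthogonalized), z superior (toward the vertex). Right-handed and
#' orthonormal; the ear-axis sign is chosen so that Cz0 has positive z.
#'
#' @param fid [fiducials].
#' @return list with `origin` (column vector) and `axes` (3 x 3, rows x/y/z);
#'   `to_frame(p)` maps world to frame coordinates.
#' @export
canonical_frame <- function(fid) {
  origin <- (fid$lpa + fid$rpa) / 2
  x <- fid$rpa - fid$lpa
  x <- x / sqrt(sum(x^2))
  y <- fid$nz - origin
  y <- y - sum(y * x) * x
  ny <- sqrt(sum(y^2))
  if (ny < 1e-9) stop("degenerate fiducials: Nz on the ear axis")
  y <- y / ny
  z <- pracma_cross(x, y)
  if (sum(z * (fid$cz0 - origin)) < 0) {
    x <- -x
    z <- -z
  }
  axes <- rbind(x = x, y = y, z = z)
  frame <- list(origin = matrix(origin, 3, 1), axes = axes)
  frame$to_frame <- function(p) {
    p <- rbind(p)
    t(axes %*% (t(p) - matrix(origin, 3, nrow(p))))
  }
  frame$from_frame <- function(p) {
    p <- rbind(p)
    t(crossprod(axes, t(p)) + matrix(origin, 3, nrow(p)))
  }
  frame
}

# ------------------------------------------------------------------- dual

#' Dual (polygonal) mesh
#'
#' One dual vertex per input face (its centroid) and one dual polygon per
#' input vertex (the ring of incident face centroids in cyclic order).
#'
#' @param mesh closed, manifold, consistently oriented [trimesh].
#' @return a [polymesh].
#' @export
dual_mesh <- function(mesh) {
  inc <- edge_incidence(mesh)
  if (any(inc != 2L))
    stop("dual_mesh requires a closed manifold mesh")
  f <- mesh$faces
  centroids <- (mesh$vertices[f[, 1], ] + mesh$vertices[f[, 2], ] +
                mesh$vertices[f[, 3], ]) / 3
  nf <- nrow(f)
  # directed edge (a,b) -> owning face
  de_from <- c(f[, 1], f[, 2], f[, 3])
  de_to <- c(f[, 2], f[, 3], f[, 1])
  de_face <- rep(seq_len(nf), 3)
  dkey <- paste(de_from, de_to)
  face_of <- function(a, b) {
    i <- match(paste(a, b), dkey)
    if (is.na(i)) NULL else de_face[i]
  }
  # vertex -> one incident face and the successor vertex inside it
  nv <- nrow(mesh$vertices)
  polys <- vector("list", nv)
  start_face <- integer(nv)
  start_face[f[, 1]] <- seq_len(nf)
  start_face[f[, 2]] <- seq_len(nf)
  start_face[f[, 3]] <- seq_len(nf)
  for (v in seq_len(nv)) {
    f0 <- start_face[v]
    if (f0 == 0L) next
    ring <- integer(0)
    fcur <- f0
    repeat {
      ring <- c(ring, fcur)
      verts <- f[fcur, ]
      i <- which(verts == v)
      prev <- verts[(i - 2L) %% 3L + 1L]       # vertex before v in the cycle
      fnext <- face_of(v, prev)                # neighbor across edge (prev,v)
      if (is.null(fnext) || fnext == f0) break
      fcur <- fnext
      if (length(ring) > 64L) stop("dual_mesh: runaway vertex ring")
    }
    polys[[v]] <- ring
  }
  polymesh(centroids, polys[!vapply(polys, is.null, TRUE)])
}

# --------------------------------------------------------------- coarsening

#' Coarsen a closed mesh by edge collapse
#'
#' Shortest-edge-first collapse (to edge midpoints, with manifoldness and
#' triangle-flip guards) until at most `keep_ratio` of the original edges
#' remain. The sampled Hausdorff distance to the input is attached as the
#' `"hausdorff"` attribute.
#'
#' @param mesh closed [trimesh].
#' @param keep_ratio fraction of edges to keep, in (0, 1].
#' @return coarsened closed [trimesh].
#' @export
coarsen <- function(mesh, keep_ratio) {
  if (keep_ratio <= 0 || keep_ratio > 1) stop("keep_ratio must be in (0, 1]")
  if (keep_ratio == 1) return(mesh)
  e0 <- nrow(mesh_edges(mesh))
  target <- max(6L, as.integer(ceiling(keep_ratio * e0)))
  res <- cpp_decimate(mesh$vertices, mesh$faces - 1L, target)
  out <- trimesh(res$vertices, res$faces + 1L)
  if (!mesh_is_closed(out))
    stop("coarsening broke closedness; increase keep_ratio")
  achieved <- nrow(mesh_edges(out))
  if (achieved > target * 1.5)
    stop(sprintf("could not reach keep_ratio %.4g; minimum achievable ~ %.4g",
                 keep_ratio, achieved / e0))
  attr(out, "hausdorff") <- mesh_hausdorff(mesh, out, n = 2000)
  out
}

#' Snap landmarks to their nearest points on a target surface
#'
#' @param landmarks a [landmark_set].
#' @param mesh target [trimesh] (typically the coarsened cap body).
#' @param warn_dist log a warning for snap distances beyond this bound (mm).
#' @return the landmark set with positions snapped; per-label snap distances
#'   in the `snap_dist` field.
#' @export
register_landmarks <- function(landmarks, mesh, warn_dist = 5) {
  res <- mesh_nearest_point(landmarks$positions, mesh)
  out <- landmarks
  rownames(res$points) <- rownames(landmarks$positions)
  out$positions <- res$points
  out$snap_dist <- structure(res$dist, names = rownames(landmarks$positions))
  far <- which(res$dist > warn_dist)
  for (i in far)
    warning(sprintf("landmark %s snapped %.2f mm (> %.2f mm)",
                    rownames(landmarks$positions)[i], res$dist[i], warn_dist))
  out
}

# ---------------------------------------------------------------- grommets

# rotation taking +z to unit vector n (Rodrigues)
rotation_to <- function(n) {
  z <- c(0, 0, 1)
  v <- pracma_cross(z, n)
  s <- sqrt(sum(v^2))
  c_ <- sum(z * n)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))      # 180 degrees about x
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

cylinder_mesh <- function(center, axis, radius, depth, segments = 24) {
  th <- 2 * pi * (seq_len(segments) - 1) / segments
  ring <- cbind(radius * cos(th), radius * sin(th))
  R <- rotation_to(axis / sqrt(sum(axis^2)))
  bot <- cbind(ring, -depth / 2)
  top <- cbind(ring, depth / 2)
  v <- rbind(bot, top, c(0, 0, -depth / 2), c(0, 0, depth / 2))
  v <- v %*% t(R)
  v <- sweep(v, 2, center, "+")
  n <- segments
  i <- seq_len(n); j <- i %% n + 1L
  side <- rbind(cbind(i, j, n + j), cbind(i, n + j, n + i))
  bcap <- cbind(2L * n + 1L, j, i)
  tcap <- cbind(2L * n + 2L, n + i, n + j)
  trimesh(v, rbind(side, bcap, tcap))
}

# interpolated outward surface normal at the point nearest to p
surface_normal_at <- function(mesh, p, vnormals = NULL) {
  if (is.null(vnormals)) vnormals <- mesh_vertex_normals(mesh)
  res <- mesh_nearest_point(p, mesh)
  fidx <- res$face[1]
  tri <- mesh$faces[fidx, ]
  a <- mesh$vertices[tri[1], ]; b <- mesh$vertices[tri[2], ]
  c_ <- mesh$vertices[tri[3], ]
  q <- res$points[1, ]
  # barycentric coordinates of q
  v0 <- b - a; v1 <- c_ - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  if (abs(den) < 1e-300) { w <- c(1, 0, 0) } else {
    bv <- (d11 * d20 - d01 * d21) / den
    bw <- (d00 * d21 - d01 * d20) / den
    w <- c(1 - bv - bw, bv, bw)
  }
  nrm <- w[1] * vnormals[tri[1], ] + w[2] * vnormals[tri[2], ] +
    w[3] * vnormals[tri[3], ]
  nrm / sqrt(sum(nrm^2))
}

#' Build grommet cutter solids at each landmark
#'
#' One closed cylindrical (or prism) cutter per landmark, centered at the
#' landmark and aligned with the outward surface normal interpolated at that
#' point.
#'
#' @param mesh the cap body surface the landmarks are registered to.
#' @param landmarks a (registered) [landmark_set].
#' @param spec a [grommet_spec].
#' @return list of cutter [trimesh] solids; each carries `center`, `axis`,
#'   `radius`, `depth` and `label` attributes.
#' @export
place_grommets <- function(mesh, landmarks, spec = grommet_spec()) {
  vn <- mesh_vertex_normals(mesh)
  P <- landmarks$positions
  cutters <- vector("list", nrow(P))
  for (i in seq_len(nrow(P))) {
    n <- surface_normal_at(mesh, P[i, ], vn)
    cut <- cylinder_mesh(P[i, ], n, spec$radius, spec$cutter_depth,
                         spec$segments)
    attr(cut, "center") <- P[i, ]
    attr(cut, "axis") <- n
    attr(cut, "radius") <- spec$radius
    attr(cut, "depth") <- spec$cutter_depth
    attr(cut, "label") <- rownames(P)[i]
    cutters[[i]] <- cut
  }
  # overlapping cutters
  if (nrow(P) > 1) {
    dmat <- as.matrix(stats::dist(P))
    ov <- which(dmat < 2 * spec$radius & upper.tri(dmat), arr.ind = TRUE)
    if (nrow(ov))
      warning("overlapping grommet cutters: ",
              paste(sprintf("%s-%s", rownames(P)[ov[, 1]],
                            rownames(P)[ov[, 2]]), collapse = ", "))
  }
  cutters
}

# ----------------------------------- conforming refinement and field cutting

# marked-edge conforming refinement: split every face whose longest edge is
# marked; closure guarantees conformity (no T-vertices).
refine_marked <- function(mesh, need_split, max_rounds = 24) {
  v <- mesh$vertices
  f <- mesh$faces
  for (round in seq_len(max_rounds)) {
    tofix <- need_split(trimesh(v, f, validate = FALSE))
    if (!any(tofix)) break
    nv <- nrow(v)
    ek <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    el2 <- function(a, b) rowSums((v[a, , drop = FALSE] - v[b, , drop = FALSE])^2)
    # longest edge per face
    l12 <- el2(f[, 1], f[, 2]); l23 <- el2(f[, 2], f[, 3]); l31 <- el2(f[, 3], f[, 1])
    lidx <- max.col(cbind(l12, l23, l31), ties.method = "first")
    longest_key <- ifelse(lidx == 1, ek(f[, 1], f[, 2]),
                          ifelse(lidx == 2, ek(f[, 2], f[, 3]), ek(f[, 3], f[, 1])))
    marked <- unique(longest_key[tofix])
    # conformity needs no closure: both faces flanking a marked edge split it
    # at the same shared midpoint (1/2/3-marked cases below)
    # midpoints for marked edges
    k12 <- ek(f[, 1], f[, 2]); k23 <- ek(f[, 2], f[, 3]); k31 <- ek(f[, 3], f[, 1])
    allk <- c(k12, k23, k31)
    alla <- c(f[, 1], f[, 2], f[, 3]); allb <- c(f[, 2], f[, 3], f[, 1])
    sel <- allk %in% marked & !duplicated(allk)
    mk <- allk[sel]
    mids <- (v[alla[sel], , drop = FALSE] + v[allb[sel], , drop = FALSE]) / 2
    mid_id <- structure(nv + seq_along(mk), names = sprintf("%.0f", mk))
    v <- rbind(v, mids)
    getmid <- function(keys) unname(mid_id[sprintf("%.0f", keys)])
    m1 <- k12 %in% marked; m2 <- k23 %in% marked; m3 <- k31 %in% marked
    touched <- which(m1 | m2 | m3)
    newf <- vector("list", length(touched))
    for (j in seq_along(touched)) {
      i <- touched[j]
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      mm <- c(m1[i], m2[i], m3[i])
      mab <- if (mm[1]) getmid(k12[i]) else NA
      mbc <- if (mm[2]) getmid(k23[i]) else NA
      mca <- if (mm[3]) getmid(k31[i]) else NA
      newf[[j]] <- switch(sum(mm),
        `1` = if (mm[1]) rbind(c(a, mab, c_), c(mab, b, c_))
              else if (mm[2]) rbind(c(b, mbc, a), c(mbc, c_, a))
              else rbind(c(c_, mca, b), c(mca, a, b)),
        `2` = if (!mm[1]) rbind(c(mbc, c_, mca), c(a, b, mbc), c(a, mbc, mca))
              else if (!mm[2]) rbind(c(a, mab, mca), c(mab, b, c_), c(mab, c_, mca))
              else rbind(c(b, mbc, mab), c(a, mab, mbc), c(a, mbc, c_)),
        `3` = rbind(c(a, mab, mca), c(mab, b, mbc), c(mca, mbc, c_),
                    c(mab, mbc, mca)))
    }
    f <- rbind(f[-touched, , drop = FALSE], do.call(rbind, newf))
    storage.mode(f) <- "integer"
  }
  trimesh(v, f)
}

# split mesh edges where the scalar vertex field crosses zero; returns the
# refined mesh plus the field extended to the new vertices (zero there).
mesh_split_by_field <- function(mesh, g) {
  v <- mesh$vertices
  f <- mesh$faces
  eps <- 1e-12 * max(abs(g), 1)
  g[abs(g) < eps] <- eps
  nv <- nrow(v)
  ek <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
  k12 <- ek(f[, 1], f[, 2]); k23 <- ek(f[, 2], f[, 3]); k31 <- ek(f[, 3], f[, 1])
  cr <- function(a, b) (g[a] > 0) != (g[b] > 0)
  c12 <- cr(f[, 1], f[, 2]); c23 <- cr(f[, 2], f[, 3]); c31 <- cr(f[, 3], f[, 1])
  allk <- c(k12[c12], k23[c23], k31[c31])
  alla <- c(f[c12, 1], f[c23, 2], f[c31, 3])
  allb <- c(f[c12, 2], f[c23, 3], f[c31, 1])
  sel <- !duplicated(allk)
  mk <- allk[sel]; ua <- alla[sel]; ub <- allb[sel]
  if (!length(mk)) return(list(mesh = mesh, g = g))
  t <- g[ua] / (g[ua] - g[ub])
  pts <- v[ua, , drop = FALSE] + t * (v[ub, , drop = FALSE] - v[ua, , drop = FALSE])
  mid_id <- structure(nv + seq_along(mk), names = sprintf("%.0f", mk))
  getmid <- function(keys) unname(mid_id[sprintf("%.0f", keys)])
  v2 <- rbind(v, pts)
  g2 <- c(g, rep(0, length(mk)))
  # exactly two edges of a triangle cross a continuous field's zero level
  touched <- which((c12 + c23 + c31) == 2L)
  newf <- vector("list", length(touched))
  for (j in seq_along(touched)) {
    i <- touched[j]
    mm <- c(c12[i], c23[i], c31[i])
    a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
    if (mm[1] && mm[2]) {          # crossings on ab and bc: b isolated
      p <- getmid(k12[i]); q <- getmid(k23[i])
      newf[[j]] <- rbind(c(b, q, p), c(a, p, q), c(a, q, c_))
    } else if (mm[2] && mm[3]) {   # bc and ca: c isolated
      p <- getmid(k23[i]); q <- getmid(k31[i])
      newf[[j]] <- rbind(c(c_, q, p), c(b, p, q), c(b, q, a))
    } else {                       # ab and ca: a isolated
      p <- getmid(k31[i]); q <- getmid(k12[i])
      newf[[j]] <- rbind(c(a, q, p), c(b, p, q), c(b, c_, p))
    }
  }
  f2 <- if (length(touched))
    rbind(f[-touched, , drop = FALSE], do.call(rbind, newf)) else f
  storage.mode(f2) <- "integer"
  list(mesh = trimesh(v2, f2, validate = FALSE), g = g2)
}

# delete faces on the negative side of a vertex field
mesh_drop_negative <- function(mesh, g) {
  s <- g[mesh$faces[, 1]] + g[mesh$faces[, 2]] + g[mesh$faces[, 3]]
  mesh_drop_unreferenced(trimesh(mesh$vertices,
                                 mesh$faces[s >= 0, , drop = FALSE],
                                 validate = FALSE))
}

point_line_dist <- function(p, origin, axis) {
  rel <- sweep(p, 2, origin)
  along <- as.numeric(rel %*% axis)
  perp <- rel - outer(along, axis)
  list(radial = sqrt(rowSums(perp^2)), axial = along)
}

#' Cut grommet holes into the cap surface
#'
#' For each cutter the cap is locally refined (conforming marked-edge
#' bisection) until the triangles around the cutter outline are finer than
#' the grommet radius, the surface is re-triangulated exactly along the
#' cutter wall, and the interior disk is removed, leaving one new boundary
#' loop per cutter.
#'
#' @param mesh cap surface [trimesh].
#' @param cutters list of cutter solids from [place_grommets()].
#' @return [trimesh] with one additional boundary loop per cutter.
#' @export
cut_grommet_holes <- function(mesh, cutters) {
  if (!length(cutters)) return(mesh)
  for (ci in seq_along(cutters)) {
    if (is.null(attr(cutters[[ci]], "center")) ||
        is.null(attr(cutters[[ci]], "axis")))
      stop("cutter ", ci, " lacks placement attributes (use place_grommets)")
  }
  centers <- t(vapply(cutters, function(cut) attr(cut, "center"), numeric(3)))
  axes <- t(vapply(cutters, function(cut) attr(cut, "axis"), numeric(3)))
  radii <- vapply(cutters, function(cut) attr(cut, "radius"), numeric(1))
  depths <- vapply(cutters, function(cut) attr(cut, "depth"), numeric(1))
  # one conforming refinement pass covering all cutter outlines
  near_fun <- function(m) {
    tc <- tri_corners(m)
    el <- pmax(rowSums((tc$a - tc$b)^2), rowSums((tc$b - tc$c)^2),
               rowSums((tc$c - tc$a)^2))
    need <- rep(FALSE, length(el))
    cen <- (tc$a + tc$b + tc$c) / 3
    for (ci in seq_along(cutters)) {
      # faces whose vertices straddle the cutter wall radius ...
      ra <- point_line_dist(tc$a, centers[ci, ], axes[ci, ])
      rb <- point_line_dist(tc$b, centers[ci, ], axes[ci, ])
      rc <- point_line_dist(tc$c, centers[ci, ], axes[ci, ])
      rmin <- pmin(ra$radial, rb$radial, rc$radial)
      rmax <- pmax(ra$radial, rb$radial, rc$radial)
      inax <- pmin(abs(ra$axial), abs(rb$axial), abs(rc$axial)) < depths[ci] / 2
      crossing <- rmin < radii[ci] & rmax > radii[ci]
      # ... or that may contain the cutter outline without straddling it
      # (coarse faces larger than the grommet): sampled center proximity
      dctr2 <- pmin(rowSums(sweep(tc$a, 2, centers[ci, ])^2),
                    rowSums(sweep(tc$b, 2, centers[ci, ])^2),
                    rowSums(sweep(tc$c, 2, centers[ci, ])^2),
                    rowSums(sweep(cen, 2, centers[ci, ])^2))
      # only relevant while faces are larger than the grommet outline
      contains <- sqrt(dctr2) < radii[ci] + 0.5 * sqrt(el) &
        el > (2 * radii[ci])^2
      need <- need | (inax & (crossing | contains) & el > (0.7 * radii[ci])^2)
    }
    need
  }
  e0 <- mesh_edges(mesh)
  base_min <- min(sqrt(rowSums((mesh$vertices[e0[, 1], , drop = FALSE] -
                                mesh$vertices[e0[, 2], , drop = FALSE])^2)))
  out <- refine_marked(mesh, near_fun)
  for (ci in seq_along(cutters)) {
    res <- tryCatch({
      pl <- point_line_dist(out$vertices, centers[ci, ], axes[ci, ])
      g <- pmax(pl$radial - radii[ci], abs(pl$axial) - depths[ci] / 2)
      sp <- mesh_split_by_field(out, g)        # negative inside the cutter
      mesh_drop_negative(sp$mesh, sp$g)
    }, error = function(e)
      stop("Boolean hole cut failed for cutter ", ci, " (",
           attr(cutters[[ci]], "label"), "): ", conditionMessage(e)))
    out <- res
  }
  # the design lattice pitch before hole cutting, for the wireframe guard
  attr(out, "base_edge_min") <- min(attr(mesh, "base_edge_min") %||% Inf,
                                    base_min)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Open the cap margins (face opening and neck rim)
#'
#' Works in the canonical head frame: removes a face box centered (in x) on
#' the nasion with width `face_width_fraction` x head width, then everything
#' below the `neck_height_fraction` plane, and optionally an ear relief band
#' above each preauricular point. Cuts re-triangulate the surface along the
#' cut outline, so rims are clean polylines.
#'
#' @param mesh cap surface [trimesh] (closed or already holed).
#' @param fid [fiducials] defining the canonical frame.
#' @param params a [cap_params].
#' @return open [trimesh] cap.
#' @export
cut_margins <- function(mesh, fid, params = cap_params()) {
  frame <- canonical_frame(fid)
  local <- frame$to_frame(mesh$vertices)
  zmin <- min(local[, 3]); zmax <- max(local[, 3])
  height <- zmax - zmin
  width <- diff(range(local[, 1]))
  nz_local <- drop(frame$to_frame(fid$nz))
  cz_local <- drop(frame$to_frame(fid$cz0))

  # face box: centered on Nz in x, in front of the ear plane, up to the brow
  half_w <- width * params$face_width_fraction / 2
  z_top <- zmin + height * params$face_height_fraction
  g_face <- pmax(abs(local[, 1] - nz_local[1]) - half_w,
                 -(local[, 2] - 1e-6 * height),      # y > 0: front half
                 local[, 3] - z_top)
  sp <- mesh_split_by_field(mesh, g_face)            # negative inside the box
  out <- mesh_drop_negative(sp$mesh, sp$g)

  # neck plane
  local <- frame$to_frame(out$vertices)
  z_cut <- zmin + height * params$neck_height_fraction
  sp <- mesh_split_by_field(out, local[, 3] - z_cut)
  out <- mesh_drop_negative(sp$mesh, sp$g)

  if (isTRUE(params$ear_cutout)) {
    for (side in list(fid$lpa, fid$rpa)) {
      p_local <- drop(frame$to_frame(side))
      local <- frame$to_frame(out$vertices)
      g_ear <- pmax(abs(local[, 2] - p_local[2]) - 0.18 * height,
                    local[, 3] - (p_local[3] + 0.22 * height),
                    -(abs(local[, 1]) - 0.38 * width))
      sp <- mesh_split_by_field(out, g_ear)
      out <- mesh_drop_negative(sp$mesh, sp$g)
    }
  }
  # sanity: the vertex region must survive
  local <- frame$to_frame(out$vertices)
  if (!nrow(local) || max(local[, 3]) < cz_local[3] - 1e-6)
    stop("margin cuts removed the vertex; relax the cut parameters")
  if (mesh_area(out) < 0.4 * mesh_area(mesh))
    stop("margin cuts removed more than 60% of the surface")
  attr(out, "base_edge_min") <- attr(mesh, "base_edge_min")
  out
}

#' Tag edges near the cap boundary for double wire thickness
#'
#' @param cap open [trimesh] with at least one boundary loop.
#' @param band_width tag edges with an endpoint within this Euclidean
#'   distance of any boundary loop (mm).
#' @param min_loop_length boundary loops shorter than this (mm) are treated
#'   as grommet rings, not exterior margins, and do not attract tags.
#' @return the cap with a logical `margin_tags` attribute (one per row of
#'   `mesh_edges(cap)`).
#' @export
thicken_margin <- function(cap, band_width = 10, min_loop_length = 60) {
  loops <- mesh_boundary_loops(cap)
  if (!length(loops)) stop("thicken_margin: mesh has no boundary (closed)")
  edges <- mesh_edges(cap)
  if (band_width <= 0) {
    attr(cap, "margin_tags") <- rep(FALSE, nrow(edges))
    return(cap)
  }
  # exterior margin = long boundary loops (face opening, neck rim, ear
  # cut-outs); short loops are grommet rings and keep single thickness
  loop_len <- vapply(loops, function(lp) {
    p <- cap$vertices[lp, , drop = FALSE]
    q <- cap$vertices[c(lp[-1], lp[1]), , drop = FALSE]
    sum(sqrt(rowSums((p - q)^2)))
  }, numeric(1))
  loops <- loops[loop_len >= min_loop_length]
  if (!length(loops)) {
    attr(cap, "margin_tags") <- rep(FALSE, nrow(edges))
    return(cap)
  }
  # distance from every vertex to the boundary polylines
  segs_a <- NULL; segs_b <- NULL
  for (lp in loops) {
    a <- cap$vertices[lp, , drop = FALSE]
    b <- cap$vertices[c(lp[-1], lp[1]), , drop = FALSE]
    segs_a <- rbind(segs_a, a); segs_b <- rbind(segs_b, b)
  }
  vd <- rep(Inf, nrow(cap$vertices))
  for (s in seq_len(nrow(segs_a))) {
    a <- segs_a[s, ]; b <- segs_b[s, ]
    ab <- b - a
    denom <- sum(ab^2)
    rel <- sweep(cap$vertices, 2, a)
    t <- if (denom > 0) pmin(1, pmax(0, as.numeric(rel %*% ab) / denom)) else 0
    q <- outer(t, ab)
    d2 <- rowSums((rel - q)^2)
    vd <- pmin(vd, d2)
  }
  vd <- sqrt(vd)
  tags <- vd[edges[, 1]] <= band_width | vd[edges[, 2]] <= band_width
  attr(cap, "margin_tags") <- tags
  cap
}

# ---------------------------------------------------------------- wireframe

mesh_edge_list <- function(cap) {
  if (inherits(cap, "polymesh")) {
    e <- do.call(rbind, lapply(cap$faces, function(p)
      cbind(p, c(p[-1], p[1]))))
    unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  } else {
    mesh_edges(cap)
  }
}

#' Extrude the cap lattice into a printable wireframe solid
#'
#' Every retained edge becomes a solid round strut (capsule) of diameter
#' `wire_thickness` (doubled on margin-tagged edges); struts fuse at shared
#' vertices through their spherical end caps. The strut union is re-tessellated
#' through a signed-distance voxelization at `pitch`, which resolves all
#' strut-strut intersections into a single closed manifold surface.
#'
#' @param cap open [trimesh] or [polymesh] cap (with holes already cut).
#' @param wire_thickness strut diameter (mm).
#' @param margin_tags optional logical vector per edge (from
#'   [thicken_margin()]; taken from the attribute when present).
#' @param pitch voxel pitch of the re-tessellation (mm); default
#'   `wire_thickness / 4`.
#' @return closed [trimesh] solid.
#' @export
wireframe <- function(cap, wire_thickness = 2.5, margin_tags = NULL,
                      pitch = NULL) {
  edges <- mesh_edge_list(cap)
  if (!nrow(edges)) stop("cap has no edges")
  if (is.null(margin_tags)) margin_tags <- attr(cap, "margin_tags")
  if (is.null(margin_tags)) margin_tags <- rep(FALSE, nrow(edges))
  if (length(margin_tags) != nrow(edges))
    stop("margin_tags length does not match edge count")
  if (is.null(pitch)) pitch <- wire_thickness / 4
  # guard: lattice (non-boundary) edges must be at least 2x the wire
  elen <- sqrt(rowSums((cap$vertices[edges[, 1], , drop = FALSE] -
                        cap$vertices[edges[, 2], , drop = FALSE])^2))
  # guard against wires swallowing the lattice openings: compare against the
  # design lattice pitch (the pre-cut minimum edge, carried through by the
  # cutting stages); grommet rings and their transition slivers deliberately
  # carry finer edges that fuse into solid collars.
  ref_len <- attr(cap, "base_edge_min")
  if (is.null(ref_len)) {
    if (inherits(cap, "trimesh")) {
      be <- mesh_boundary_edges(cap)
      bverts <- unique(as.vector(be))
      lattice <- !(edges[, 1] %in% bverts | edges[, 2] %in% bverts)
    } else lattice <- rep(TRUE, nrow(edges))
    ref_len <- if (any(lattice)) min(elen[lattice]) else min(elen)
  }
  if (wire_thickness > ref_len / 2)
    stop(sprintf(paste0("wire_thickness %.2f mm exceeds half the shortest ",
                        "lattice edge (%.2f mm); use a coarser keep_ratio"),
                 wire_thickness, ref_len))
  radius <- ifelse(margin_tags, wire_thickness, wire_thickness / 2)
  seg_a <- cap$vertices[edges[, 1], , drop = FALSE]
  seg_b <- cap$vertices[edges[, 2], , drop = FALSE]
  solidify_capsules(seg_a, seg_b, radius, pitch)
}

# marching-tetrahedra surface of a union of capsules
solidify_capsules <- function(seg_a, seg_b, radius, pitch) {
  lo <- pmin(apply(seg_a, 2, min), apply(seg_b, 2, min)) - max(radius) - 4 * pitch
  hi <- pmax(apply(seg_a, 2, max), apply(seg_b, 2, max)) + max(radius) + 4 * pitch
  dims <- as.integer(ceiling((hi - lo) / pitch)) + 1L
  if (prod(as.numeric(dims)) > 4e8)
    stop("voxel grid too large; increase pitch")
  field <- cpp_capsule_field(seg_a, seg_b, radius, dims, lo, pitch)
  mt <- cpp_marching_tetra(field, dims, lo, rep(pitch, 3), 0)
  out <- trimesh(mt$vertices, mt$faces + 1L, validate = FALSE)
  mt_postprocess(out, tol = 1e-6 * mesh_bbox_diag(out))
}
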