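#' Mesh defect census
#'
#' Counts every defect class that would break 3D printing: non-manifold
#' edges, boundary edges, zero-area faces, zero-length edges, duplicate
#' vertices, self-intersecting face pairs and inconsistently oriented faces,
#' plus the enclosed signed volume. A mesh is *printable* when every count is
#' zero and the volume is positive (a watertight closed surface).
#'
#' @param mesh a [trimesh].
#' @param weld_tol duplicate-vertex tolerance (mm); the default 0 counts
#'   exact duplicates only.
#' @param check_self_intersections set `FALSE` to skip the (more expensive)
#'   triangle-triangle census.
#' @return object of class `mesh_defect_report`.
#' @export
diagnose <- function(mesh, weld_tol = 0, check_self_intersections = TRUE) {
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  he_a <- c(f[, 1], f[, 2], f[, 3])
  he_b <- c(f[, 2], f[, 3], f[, 1])
  ukey <- pmin(he_a, he_b) * (nv + 1) + pmax(he_a, he_b)
  tab <- sort(ukey)
  r <- rle(tab)
  boundary_edges <- sum(r$lengths == 1L)
  non_manifold_edges <- sum(r$lengths > 2L)

  areas <- mesh_face_areas(mesh)
  diag_len <- max(mesh_bbox_diag(mesh), 1e-300)
  zero_area_faces <- sum(areas <= 1e-14 * diag_len^2)
  elen2 <- rowSums((mesh$vertices[he_a, , drop = FALSE] -
                    mesh$vertices[he_b, , drop = FALSE])^2)
  zero_length_edges <- sum(elen2[!duplicated(ukey)] == 0)

  cl <- cpp_weld_clusters(mesh$vertices, weld_tol)
  duplicate_vertices <- nv - length(unique(cl))

  inverted <- orientation_defects(mesh)
  self_int <- 0
  if (check_self_intersections && nrow(f))
    self_int <- cpp_self_intersections(mesh$vertices, f - 1L, 100L)$count

  structure(list(
    non_manifold_edges = non_manifold_edges,
    boundary_edges = boundary_edges,
    zero_area_faces = zero_area_faces,
    zero_length_edges = zero_length_edges,
    duplicate_vertices = duplicate_vertices,
    self_intersections = self_int,
    inverted_faces = inverted,
    volume = mesh_volume(mesh)
  ), class = "mesh_defect_report")
}

# number of faces whose orientation disagrees with a neighbor: faces incident
# to an interior edge traversed in the SAME direction by both faces (zero for
# consistently oriented meshes, regardless of inside-out, which the volume
# sign reports instead)
orientation_defects <- function(mesh) {
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  nf <- nrow(f)
  he_a <- c(f[, 1], f[, 2], f[, 3])
  he_b <- c(f[, 2], f[, 3], f[, 1])
  dkey <- he_a * (nv + 1) + he_b
  bad_dir <- duplicated(dkey) | duplicated(dkey, fromLast = TRUE)
  if (!any(bad_dir)) return(0L)
  length(unique(rep(seq_len(nf), 3)[bad_dir]))
}

# greedy BFS orientation: returns flip flags making adjacent faces consistent
orient_bfs <- function(mesh) {
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  nf <- nrow(f)
  he_a <- c(f[, 1], f[, 2], f[, 3])
  he_b <- c(f[, 2], f[, 3], f[, 1])
  he_face <- rep(seq_len(nf), 3)
  ukey <- pmin(he_a, he_b) * (nv + 1) + pmax(he_a, he_b)
  ord <- order(ukey)
  grp_key <- ukey[ord]
  grp_face <- he_face[ord]
  grp_dir <- (he_a < he_b)[ord]      # direction flag of the half-edge
  starts <- which(!duplicated(grp_key))
  ends <- c(starts[-1] - 1L, length(grp_key))
  # adjacency: face pairs sharing a 2-incident edge + whether dirs agree
  two <- which(ends - starts == 1L)
  fa <- grp_face[starts[two]]
  fb <- grp_face[ends[two]]
  same_dir <- grp_dir[starts[two]] == grp_dir[ends[two]]
  adj <- split(seq_along(fa), fa)
  adj_b <- split(seq_along(fb), fb)
  flip <- rep(NA, nf)
  for (seed in seq_len(nf)) {
    if (!is.na(flip[seed])) next
    flip[seed] <- FALSE
    queue <- integer(1024)
    queue[1] <- seed
    head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]
      head <- head + 1L
      ids <- c(adj[[as.character(cur)]], adj_b[[as.character(cur)]])
      for (id in ids) {
        other <- if (fa[id] == cur) fb[id] else fa[id]
        # consistent orientation means opposite directions on the shared edge
        want <- if (same_dir[id]) !flip[cur] else flip[cur]
        if (is.na(flip[other])) {
          flip[other] <- want
          tail <- tail + 1L
          if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[tail] <- other
        }
      }
    }
  }
  flip[is.na(flip)] <- FALSE
  list(flip = flip, flipped = sum(flip))
}

#' @export
print.mesh_defect_report <- function(x, ...) {
  cat("<mesh_defect_report>\n")
  for (nm in setdiff(names(x), "volume"))
    cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  cat(sprintf("  %-22s %.6g mm^3\n", "volume", x$volume))
  cat(sprintf("  printable: %s\n", is_printable(x)))
  invisible(x)
}

#' Is a defect report clean enough to print?
#' @param report a `mesh_defect_report` (or a [trimesh], which is diagnosed).
#' @export
is_printable <- function(report) {
  if (inherits(report, "trimesh")) report <- diagnose(report)
  counts <- unlist(report[setdiff(names(report), "volume")])
  all(counts == 0) && report$volume > 0
}

#' Merge vertices within a distance threshold
#'
#' Single-linkage clusters of vertices within `tolerance` collapse to their
#' centroid; faces degenerated by the merge are removed. `tolerance = 0`
#' merges exact duplicates only.
#'
#' @param mesh a [trimesh].
#' @param tolerance merge distance (mm); defaults to 1e-4 x the bounding-box
#'   diagonal.
#' @param feature_size optional smallest intended feature (e.g. half the wire
#'   thickness); the weld refuses tolerances that would erase it.
#' @return welded [trimesh].
#' @export
weld <- function(mesh, tolerance = NULL, feature_size = NULL) {
  if (is.null(tolerance)) tolerance <- 1e-4 * mesh_bbox_diag(mesh)
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (!is.null(feature_size) && tolerance >= feature_size)
    stop(sprintf("weld tolerance %.4g >= smallest feature %.4g; refused",
                 tolerance, feature_size))
  cl <- cpp_weld_clusters(mesh$vertices, tolerance) + 1L
  k <- max(cl)
  sums <- rowsum(mesh$vertices, group = cl, reorder = TRUE)
  counts <- tabulate(cl, nbins = k)
  newv <- sums / counts
  f <- matrix(cl[mesh$faces], ncol = 3)
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  trimesh(newv, f[keep, , drop = FALSE], validate = FALSE)
}

#' Repair a mesh into a watertight printable surface
#'
#' Pipeline: weld near-duplicate vertices, drop degenerate (zero-area /
#' zero-length) faces, fill small boundary loops (at most `max_hole_edges`
#' edges -- larger openings are design features and abort the repair),
#' reorient all faces consistently outward, and re-diagnose. Errors if
#' defects remain, with the residual report attached to the condition.
#'
#' @param mesh a [trimesh].
#' @param weld_tolerance merge distance (default 1e-4 x bbox diagonal).
#' @param max_hole_edges largest boundary loop that is considered an
#'   accidental hole rather than a design feature.
#' @param check_self_intersections verify the result is intersection-free.
#' @return repaired [trimesh].
#' @export
repair <- function(mesh, weld_tolerance = NULL, max_hole_edges = 12,
                   check_self_intersections = TRUE) {
  m <- weld(mesh, tolerance = weld_tolerance)
  # drop exactly-degenerate faces
  areas <- mesh_face_areas(m)
  diag_len <- max(mesh_bbox_diag(m), 1e-300)
  m <- trimesh(m$vertices, m$faces[areas > 1e-14 * diag_len^2, , drop = FALSE],
               validate = FALSE)
  # fill small holes with a centroid fan
  loops <- mesh_boundary_loops(m)
  big <- vapply(loops, length, 1L) > max_hole_edges
  if (any(big))
    stop(sprintf("repair: %d boundary loop(s) larger than %d edges; refusing to seal design openings",
                 sum(big), max_hole_edges))
  v <- m$vertices
  f <- m$faces
  for (lp in loops) {
    centroid <- colMeans(v[lp, , drop = FALSE])
    v <- rbind(v, centroid)
    cid <- nrow(v)
    # boundary half-edges run along lp in stored order; fill with opposite
    a <- lp
    b <- c(lp[-1], lp[1])
    f <- rbind(f, cbind(b, a, cid))
  }
  m <- trimesh(v, f, validate = FALSE)
  # consistent outward orientation
  ob <- orient_bfs(m)
  f <- m$faces
  f[ob$flip, ] <- f[ob$flip, c(1, 3, 2), drop = FALSE]
  m <- trimesh(m$vertices, f, validate = FALSE)
  if (mesh_volume(m) < 0) m <- trimesh(m$vertices, f[, c(1, 3, 2)], validate = FALSE)
  rep <- diagnose(m, check_self_intersections = check_self_intersections)
  if (!is_printable(rep)) {
    cond <- simpleError("repair left residual defects; see attr(.,'report')")
    attr(cond, "report") <- rep
    stop(cond)
  }
  m
}

# Cleanup for marching-tetrahedra output after welding: removes zero-volume
# duplicate-face flaps and collapses the tiny pinch edges that arise where
# two sheets of the level set touch within the weld tolerance.
mt_postprocess <- function(mesh, tol) {
  m <- weld(mesh, tolerance = tol)
  # duplicate-face flaps: faces sharing the same vertex set cancel in pairs
  flo <- pmin(m$faces[, 1], m$faces[, 2], m$faces[, 3])
  fhi <- pmax(m$faces[, 1], m$faces[, 2], m$faces[, 3])
  fmid <- m$faces[, 1] + m$faces[, 2] + m$faces[, 3] - flo - fhi
  key <- paste(flo, fmid, fhi)
  dup <- key %in% key[duplicated(key)]
  if (any(dup)) {
    drop <- integer(0)
    for (k in unique(key[dup])) {
      idx <- which(key == k)
      keep <- length(idx) %% 2L          # odd group keeps one face
      drop <- c(drop, idx[seq_len(length(idx) - keep)])
    }
    m <- trimesh(m$vertices, m$faces[-drop, , drop = FALSE], validate = FALSE)
  }
  # pinch edges: non-manifold and tiny; merge their endpoints
  for (round in 1:5) {
    nv <- nrow(m$vertices)
    f <- m$faces
    he_a <- c(f[, 1], f[, 2], f[, 3])
    he_b <- c(f[, 2], f[, 3], f[, 1])
    ukey <- pmin(he_a, he_b) * (nv + 1) + pmax(he_a, he_b)
    s <- sort(ukey)
    r <- rle(s)
    bad <- r$values[r$lengths > 2L]
    if (!length(bad)) break
    lo <- floor(bad / (nv + 1))
    hi <- bad - lo * (nv + 1)
    elen <- sqrt(rowSums((m$vertices[lo, , drop = FALSE] -
                          m$vertices[hi, , drop = FALSE])^2))
    short <- elen < 100 * tol
    if (!any(short)) break
    map <- seq_len(nv)
    map[hi[short]] <- lo[short]
    map <- map[map]                      # resolve one level of chains
    v <- m$vertices
    v[lo[short], ] <- (v[lo[short], , drop = FALSE] +
                       m$vertices[hi[short], , drop = FALSE]) / 2
    f2 <- matrix(map[f], ncol = 3)
    keep <- f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3]
    m <- trimesh(v, f2[keep, , drop = FALSE], validate = FALSE)
  }
  mesh_drop_unreferenced(m)
}

#' Re-tessellate a strut soup into one watertight solid
#'
#' Voxel-based re-meshing of an arbitrary (possibly self-intersecting) union
#' of closed solids: occupancy is computed by generalized winding along grid
#' columns, converted to a narrow-band signed-distance field and re-surfaced
#' with marching tetrahedra. Strut-strut intersections disappear into a
#' single manifold surface.
#'
#' @param wireframe_mesh input [trimesh] soup (closed components, outward
#'   normals).
#' @param voxel_pitch re-tessellation pitch (mm); must resolve the thinnest
#'   strut (wire/4 or finer).
#' @return closed [trimesh].
#' @export
remesh_solidify <- function(wireframe_mesh, voxel_pitch) {
  bb <- mesh_bbox(wireframe_mesh)
  ext <- bb[2, ] - bb[1, ]
  if (voxel_pitch <= 0) stop("voxel_pitch must be positive")
  if (voxel_pitch > min(ext[ext > 0]) / 4)
    stop("voxel_pitch too coarse for the smallest feature; reduce it")
  lo <- bb[1, ] - 4 * voxel_pitch
  dims <- as.integer(ceiling((ext + 8 * voxel_pitch) / voxel_pitch)) + 1L
  if (prod(as.numeric(dims)) > 4e8) stop("voxel grid too large; increase pitch")
  field <- cpp_resolidify_field(wireframe_mesh$vertices,
                                wireframe_mesh$faces - 1L,
                                dims, lo, voxel_pitch)
  mt <- cpp_marching_tetra(field, dims, lo, rep(voxel_pitch, 3), 0)
  out <- trimesh(mt$vertices, mt$faces + 1L, validate = FALSE)
  mt_postprocess(out, tol = 1e-6 * mesh_bbox_diag(out))
}
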