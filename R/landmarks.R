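#' Cranial fiducials
#'
#' The five user-specified reference points anchoring the 10-20 construction:
#' nasion (Nz), inion (Iz), left/right preauricular points (LPA/RPA) and an
#' initial vertex estimate (Cz0).
#'
#' @param nz,iz,lpa,rpa,cz0 length-3 numeric positions (mm).
#' @return an object of class `fiducials`.
#' @export
fiducials <- function(nz, iz, lpa, rpa, cz0) {
  pts <- list(nz = nz, iz = iz, lpa = lpa, rpa = rpa, cz0 = cz0)
  pts <- lapply(pts, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || anyNA(p)) stop("fiducials must be finite 3-vectors")
    p
  })
  if (sqrt(sum((pts$nz - pts$iz)^2)) < 1e-12) stop("Nz and Iz coincide")
  if (sqrt(sum((pts$lpa - pts$rpa)^2)) < 1e-12) stop("LPA and RPA coincide")
  structure(pts, class = "fiducials")
}

#' @export
print.fiducials <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%-4s %s\n", toupper(nm), paste(signif(x[[nm]], 6), collapse = " ")))
  invisible(x)
}

transform_fiducials <- function(fid, rotation = diag(3), translation = c(0, 0, 0)) {
  out <- lapply(unclass(fid), function(p) as.numeric(rotation %*% p + translation))
  do.call(fiducials, out)
}

#' Arc-length parameterized surface curve
#'
#' An ordered polyline lying on a mesh: either a closed cross-section loop or
#' an open arc. `cumlen` has one entry per point for open curves, plus the
#' closing segment for closed ones.
#'
#' @param points n x 3 matrix of ordered points (mm).
#' @param closed is the curve a closed loop?
#' @return an object of class `surface_curve` with fields `points`, `closed`,
#'   `cumlen` and `length`.
#' @export
surface_curve <- function(points, closed = FALSE) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("a curve needs at least 2 points")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0)) {
    keep <- c(TRUE, seg > 0)
    points <- points[keep, , drop = FALSE]
    seg <- seg[seg > 0]
  }
  cum <- c(0, cumsum(seg))
  if (closed) {
    wrap <- sqrt(sum((points[1, ] - points[nrow(points), ])^2))
    cum <- c(cum, cum[length(cum)] + wrap)
  }
  structure(list(points = points, closed = closed, cumlen = cum,
                 length = cum[length(cum)]),
            class = "surface_curve")
}

#' @export
print.surface_curve <- function(x, ...) {
  cat(sprintf("<surface_curve> %d points, %s, length %.4g mm\n",
              nrow(x$points), if (x$closed) "closed" else "open", x$length))
  invisible(x)
}

# ------------------------------------------------------------ cross-section

#' Plane/mesh cross-section loop
#'
#' Intersects the plane through `p1`, `p2`, `p3` with a closed mesh and
#' returns the crossing polyline as a closed [surface_curve]. When the plane
#' cuts the mesh in several loops, the loop minimizing the summed distance to
#' the three defining points is returned.
#'
#' @param mesh a closed [trimesh].
#' @param p1,p2,p3 non-collinear points defining the plane (mm).
#' @return closed [surface_curve].
#' @export
cross_section <- function(mesh, p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  n <- pracma_cross(p2 - p1, p3 - p1)
  nn <- sqrt(sum(n^2))
  scale <- max(sqrt(sum((p2 - p1)^2)), sqrt(sum((p3 - p1)^2)))
  if (nn < 1e-12 * scale^2) stop("cross_section: defining points are collinear")
  n <- n / nn
  v <- mesh$vertices
  d <- as.numeric((v - matrix(p1, nrow(v), 3, byrow = TRUE)) %*% n)
  eps <- 1e-12 * max(mesh_bbox_diag(mesh), 1e-12)
  d[abs(d) < eps] <- eps                       # nudge on-plane vertices
  f <- mesh$faces
  s1 <- d[f[, 1]] > 0; s2 <- d[f[, 2]] > 0; s3 <- d[f[, 3]] > 0
  crossed <- which((s1 != s2) | (s2 != s3))
  if (!length(crossed)) stop("cross_section: plane does not intersect the mesh")

  nv <- nrow(v)
  ekey <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
  # for every crossed face, its two crossing edges
  fc <- f[crossed, , drop = FALSE]
  pair_edges <- matrix(NA_real_, length(crossed), 2)
  edge_a <- matrix(NA_integer_, length(crossed), 2)
  edge_b <- matrix(NA_integer_, length(crossed), 2)
  combos <- list(c(1, 2), c(2, 3), c(3, 1))
  cnt <- rep(0L, length(crossed))
  for (cb in combos) {
    a <- fc[, cb[1]]; b <- fc[, cb[2]]
    cr <- (d[a] > 0) != (d[b] > 0)
    idx <- which(cr)
    slot <- cnt[idx] + 1L
    for (k in seq_along(idx)) {
      i <- idx[k]
      pair_edges[i, slot[k]] <- ekey(a[i], b[i])
      edge_a[i, slot[k]] <- a[i]
      edge_b[i, slot[k]] <- b[i]
    }
    cnt[idx] <- slot
  }
  # crossing point per unique edge
  all_keys <- c(pair_edges[, 1], pair_edges[, 2])
  all_a <- c(edge_a[, 1], edge_a[, 2]); all_b <- c(edge_b[, 1], edge_b[, 2])
  first <- !duplicated(all_keys)
  ukeys <- all_keys[first]
  ua <- all_a[first]; ub <- all_b[first]
  t <- d[ua] / (d[ua] - d[ub])
  pts <- v[ua, , drop = FALSE] + t * (v[ub, , drop = FALSE] - v[ua, , drop = FALSE])
  eid <- function(keys) match(keys, ukeys)
  e1 <- eid(pair_edges[, 1]); e2 <- eid(pair_edges[, 2])

  # chain crossed faces into loops: each face links its two edge-points
  nedge <- length(ukeys)
  adj <- vector("list", nedge)
  for (i in seq_along(crossed)) {
    adj[[e1[i]]] <- c(adj[[e1[i]]], e2[i])
    adj[[e2[i]]] <- c(adj[[e2[i]]], e1[i])
  }
  visited <- rep(FALSE, nedge)
  loops <- list()
  for (start in seq_len(nedge)) {
    if (visited[start]) next
    loop <- integer(0)
    cur <- start; prev <- 0L
    repeat {
      visited[cur] <- TRUE
      loop <- c(loop, cur)
      nxt <- setdiff(adj[[cur]], prev)
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break
      prev <- cur
      cur <- nxt[1]
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  if (!length(loops)) stop("cross_section: degenerate intersection")
  if (length(loops) > 1L) {
    anchors <- rbind(p1, p2, p3)
    score <- vapply(loops, function(lp) {
      lpts <- pts[lp, , drop = FALSE]
      sum(apply(anchors, 1, function(q) {
        min(sqrt(rowSums((lpts - matrix(q, nrow(lpts), 3, byrow = TRUE))^2)))
      }))
    }, numeric(1))
    loops <- loops[order(score)]
  }
  surface_curve(pts[loops[[1]], , drop = FALSE], closed = TRUE)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ------------------------------------------------------- curve parameterics

# nearest position on a polyline; returns arc-length parameter and point
curve_project <- function(curve, p) {
  pts <- curve$points
  n <- nrow(pts)
  a <- pts
  b <- if (curve$closed) pts[c(2:n, 1), , drop = FALSE] else pts[c(2:n, n), , drop = FALSE]
  if (!curve$closed) { a <- pts[-n, , drop = FALSE]; b <- pts[-1, , drop = FALSE] }
  ab <- b - a
  ap <- matrix(p, nrow(a), 3, byrow = TRUE) - a
  denom <- rowSums(ab^2)
  denom[denom == 0] <- 1
  t <- pmin(1, pmax(0, rowSums(ap * ab) / denom))
  q <- a + t * ab
  dd <- rowSums((q - matrix(p, nrow(a), 3, byrow = TRUE))^2)
  i <- which.min(dd)
  s <- curve$cumlen[i] + t[i] * sqrt(sum(ab[i, ]^2))
  list(s = s, point = q[i, ], dist = sqrt(dd[i]))
}

#' Point at an arc-length fraction of a curve
#'
#' @param curve a [surface_curve] with positive length.
#' @param t fraction in `[0, 1]` of the total arc length.
#' @return length-3 point, linearly interpolated within a segment.
#' @export
point_at_fraction <- function(curve, t) {
  if (!is.finite(t) || t < 0 || t > 1)
    stop("fraction must lie in [0, 1]")
  if (curve$length <= 0) stop("curve has zero length")
  target <- t * curve$length
  cum <- curve$cumlen
  pts <- curve$points
  n <- nrow(pts)
  i <- findInterval(target, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(cum) - 1L)
  p0 <- pts[i, ]
  p1 <- if (i + 1L > n) pts[1, ] else pts[i + 1L, ]   # wrap for closed curves
  seg <- cum[i + 1L] - cum[i]
  u <- if (seg > 0) (target - cum[i]) / seg else 0
  p0 + u * (p1 - p0)
}

#' Sub-arc of a closed loop through a via point
#'
#' Extracts the portion of a closed loop running from the loop position
#' nearest `a` to the position nearest `b`, in the direction that passes the
#' position nearest `via`. Endpoints are snapped to the loop.
#'
#' @param loop closed [surface_curve].
#' @param a,b,via query points (mm), each within `tol` of the loop.
#' @param tol snap tolerance (mm); default 2x the loop's mean segment length.
#' @return open [surface_curve] from `a` to `b`.
#' @export
arc_on_loop <- function(loop, a, b, via, tol = NULL) {
  stopifnot(inherits(loop, "surface_curve"), loop$closed)
  if (is.null(tol)) tol <- 2 * loop$length / nrow(loop$points)
  pa <- curve_project(loop, as.numeric(a))
  pb <- curve_project(loop, as.numeric(b))
  pv <- curve_project(loop, as.numeric(via))
  for (pr in list(a = pa, b = pb, via = pv)) {
    if (pr$dist > tol)
      stop(sprintf("arc_on_loop: point is %.4g mm from the loop (tolerance %.4g)",
                   pr$dist, tol))
  }
  if (sqrt(sum((pa$point - pb$point)^2)) < 1e-12 * max(loop$length, 1))
    stop("arc_on_loop: endpoints coincide (zero-length arc)")
  if (min(sqrt(sum((pv$point - pa$point)^2)),
          sqrt(sum((pv$point - pb$point)^2))) < 1e-12 * max(loop$length, 1))
    stop("arc_on_loop: via point coincides with an endpoint")
  L <- loop$length
  fwd_len <- (pb$s - pa$s) %% L
  via_fwd <- (pv$s - pa$s) %% L
  forward <- via_fwd <= fwd_len
  extract <- function(s0, s1) {
    # walk forward from parameter s0 to s1 (mod L)
    cum <- loop$cumlen
    n <- nrow(loop$points)
    span <- (s1 - s0) %% L
    # vertex parameters strictly inside (s0, s0+span)
    vs <- cum[seq_len(n)]
    rel <- (vs - s0) %% L
    inside <- which(rel > 1e-12 * L & rel < span - 1e-12 * L)
    ord <- inside[order(rel[inside])]
    pts <- rbind(point_on_curve_at(loop, s0),
                 loop$points[ord, , drop = FALSE],
                 point_on_curve_at(loop, (s0 + span) %% L))
    surface_curve(pts, closed = FALSE)
  }
  if (forward) extract(pa$s, pb$s) else {
    arc <- extract(pb$s, pa$s)
    surface_curve(arc$points[rev(seq_len(nrow(arc$points))), , drop = FALSE],
                  closed = FALSE)
  }
}

point_on_curve_at <- function(curve, s) {
  s <- s %% max(curve$length, 1e-300)
  point_at_fraction(curve, s / curve$length)
}

# ---------------------------------------------------------------- refine Cz

#' Iteratively refine the vertex (Cz) position
#'
#' Alternates two midpoint updates until convergence: (i) the coronal loop
#' through LPA, RPA and the current Cz is cut and Cz moves to the midpoint of
#' the LPA-Cz-RPA arc; (ii) the sagittal loop through Nz, Iz and the new Cz is
#' cut and Cz moves to the midpoint of the Nz-Cz-Iz arc. Iteration stops when
#' successive estimates move less than `tol` (default 1e-6 mesh units); a few
#' extra passes then polish the fixed point to machine precision so the result
#' is stable under rigid transforms.
#'
#' @param mesh closed head [trimesh].
#' @param fid [fiducials].
#' @param tol convergence threshold on successive Cz estimates (mesh units).
#' @param max_iter iteration cap.
#' @return list with `cz`, `iterations` (count to reach `tol`), `delta`,
#'   `sagittal_arc`, `coronal_arc`.
#' @export
refine_cz <- function(mesh, fid, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(fid, "fiducials"))
  cz <- as.numeric(fid$cz0)
  floor_tol <- 1e-13 * mesh_bbox_diag(mesh)
  iterations_to_tol <- NA_integer_
  delta <- Inf
  prev_delta <- Inf
  sag_arc <- cor_arc <- NULL
  for (it in seq_len(max_iter)) {
    cor_loop <- cross_section(mesh, fid$lpa, fid$rpa, cz)
    cor_arc <- arc_on_loop(cor_loop, fid$lpa, fid$rpa, via = cz)
    cz1 <- point_at_fraction(cor_arc, 0.5)
    sag_loop <- cross_section(mesh, fid$nz, fid$iz, cz1)
    sag_arc <- arc_on_loop(sag_loop, fid$nz, fid$iz, via = cz1)
    cz2 <- point_at_fraction(sag_arc, 0.5)
    delta <- sqrt(sum((cz2 - cz)^2))
    cz <- cz2
    if (is.na(iterations_to_tol) && delta < tol) iterations_to_tol <- it
    if (delta < floor_tol) break
    if (delta < tol && delta >= prev_delta) break   # stagnated at machine noise
    prev_delta <- delta
  }
  if (is.na(iterations_to_tol))
    stop(sprintf("refine_cz did not converge in %d iterations (last delta %.3g)",
                 max_iter, delta))
  # final arcs through the converged Cz
  cor_loop <- cross_section(mesh, fid$lpa, fid$rpa, cz)
  cor_arc <- arc_on_loop(cor_loop, fid$lpa, fid$rpa, via = cz)
  sag_loop <- cross_section(mesh, fid$nz, fid$iz, cz)
  sag_arc <- arc_on_loop(sag_loop, fid$nz, fid$iz, via = cz)
  list(cz = cz, iterations = iterations_to_tol, delta = delta,
       sagittal_arc = sag_arc, coronal_arc = cor_arc)
}

# ------------------------------------------------------------ montage table

sagittal_1010 <- data.frame(
  fraction = seq(0.1, 0.9, by = 0.1),
  label = c("Fpz", "AFz", "Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz"),
  stringsAsFactors = FALSE)

sagittal_105_extra <- data.frame(
  fraction = seq(0.05, 0.95, by = 0.1),
  label = c("NFpz", "AFpz", "AFFz", "FFCz", "FCCz", "CCPz", "CPPz", "PPOz",
            "POOz", "OIz"),
  stringsAsFactors = FALSE)

coronal_1010 <- data.frame(
  fraction = seq(0.1, 0.9, by = 0.1),
  label = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
  stringsAsFactors = FALSE)

coronal_105_extra <- data.frame(
  fraction = seq(0.15, 0.85, by = 0.1),
  label = c("T7h", "C5h", "C3h", "C1h", "C2h", "C4h", "C6h", "T8h"),
  stringsAsFactors = FALSE)

ring_left_1010 <- data.frame(
  fraction = seq(0.1, 0.9, by = 0.1),
  label = c("Fp1", "AF7", "F7", "FT7", "T7", "TP7", "P7", "PO7", "O1"),
  stringsAsFactors = FALSE)

ring_left_105_extra <- data.frame(
  fraction = seq(0.05, 0.95, by = 0.1),
  label = c("Fp1h", "AFp7", "AFF7", "FFT7", "FTT7", "TTP7", "TPP7", "PPO7",
            "POO7", "O1h"),
  stringsAsFactors = FALSE)

mirror_label <- function(label) {
  # swap odd (left) and even (right) trailing digits, preserving 'h' suffix
  vapply(label, function(l) {
    has_h <- grepl("h$", l)
    core <- sub("h$", "", l)
    m <- regmatches(core, regexec("^(.*?)([0-9]+)$", core))[[1]]
    if (length(m) == 0) return(l)
    num <- as.integer(m[3])
    swapped <- if (num %% 2 == 1) num + 1L else num - 1L
    paste0(m[2], swapped, if (has_h) "h" else "")
  }, character(1), USE.NAMES = FALSE)
}

# A landmark row: cross-section through three anchors, subdivided evenly.
# `interior` lists the labels between the outer anchors INCLUDING the middle
# anchor label (skipped at placement time since it is already positioned).
# dense = TRUE adds half-step positions named after the laterally adjacent
# label with an "h" suffix.
row_curve <- function(anchors, interior, dense = FALSE) {
  k <- length(interior) + 1L        # number of intervals
  fr <- seq_len(k - 1L) / k
  out <- list(anchors = anchors, fractions = fr, labels = interior)
  if (dense) {
    mids <- (seq_len(k) - 0.5) / k
    ref <- c(anchors[1], interior, anchors[3])
    half <- character(k)
    lefts <- seq_len(floor(k / 2))
    half[lefts] <- paste0(ref[lefts], "h")
    rights <- (floor(k / 2) + 1L):k
    half[rights] <- paste0(ref[rights + 1L], "h")
    out$fractions <- c(out$fractions, mids)
    out$labels <- c(out$labels, half)
    ord <- order(out$fractions)
    out$fractions <- out$fractions[ord]
    out$labels <- out$labels[ord]
  }
  out
}

#' Default montage construction recipe
#'
#' Declarative description of how each landmark row is generated: reference
#' sagittal/coronal fractions, the 10% horizontal ring through Fpz-T7-Oz, and
#' the intermediate rows, each a cross-section through three already-placed
#' anchors subdivided at fixed arc-length fractions. The 10-20 set is the
#' standard 21-label subset of 10-10; 10-5 doubles every subdivision (half-step
#' labels carry an `h` suffix or their standard 10-5 compound names).
#'
#' @param system `"10-20"`, `"10-10"` or `"10-5"`.
#' @return recipe list with `sagittal`, `coronal`, `curves` and optional
#'   `subset`.
#' @export
montage_recipe <- function(system = c("10-10", "10-20", "10-5")) {
  system <- match.arg(system)
  dense <- identical(system, "10-5")
  sagittal <- sagittal_1010
  coronal <- coronal_1010
  ring_left <- ring_left_1010
  if (dense) {
    sagittal <- rbind(sagittal, sagittal_105_extra)
    coronal <- rbind(coronal, coronal_105_extra)
    ring_left <- rbind(ring_left, ring_left_105_extra)
  }
  ring_right <- ring_left
  ring_right$label <- mirror_label(ring_left$label)
  sagittal <- sagittal[order(sagittal$fraction), ]
  coronal <- coronal[order(coronal$fraction), ]
  ord_l <- order(ring_left$fraction)
  ord_r <- order(ring_right$fraction)
  curves <- list(
    list(id = "ring_left", anchors = c("Fpz", "T7", "Oz"),
         fractions = ring_left$fraction[ord_l], labels = ring_left$label[ord_l]),
    list(id = "ring_right", anchors = c("Fpz", "T8", "Oz"),
         fractions = ring_right$fraction[ord_r], labels = ring_right$label[ord_r]))
  rows <- list(
    list(id = "F",  anchors = c("F7", "Fz", "F8"),
         interior = c("F5", "F3", "F1", "Fz", "F2", "F4", "F6")),
    list(id = "FC", anchors = c("FT7", "FCz", "FT8"),
         interior = c("FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6")),
    list(id = "CP", anchors = c("TP7", "CPz", "TP8"),
         interior = c("CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6")),
    list(id = "P",  anchors = c("P7", "Pz", "P8"),
         interior = c("P5", "P3", "P1", "Pz", "P2", "P4", "P6")),
    list(id = "AF", anchors = c("AF7", "AFz", "AF8"),
         interior = c("AF3", "AFz", "AF4")),
    list(id = "PO", anchors = c("PO7", "POz", "PO8"),
         interior = c("PO3", "POz", "PO4")))
  for (rw in rows) {
    rc <- row_curve(rw$anchors, rw$interior, dense = dense)
    curves[[length(curves) + 1L]] <- c(list(id = rw$id), rc)
  }
  recipe <- list(system = system, sagittal = sagittal, coronal = coronal,
                 curves = curves)
  if (identical(system, "10-20")) {
    recipe$subset <- c("Fpz", "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                       "T7", "C3", "Cz", "C4", "T8",
                       "P7", "P3", "Pz", "P4", "P8", "O1", "O2", "Oz")
  }
  recipe
}

# --------------------------------------------------------- compute landmarks

#' Labeled landmark positions
#'
#' @param system montage system id.
#' @param positions named matrix of 3D positions (rownames = labels, mm).
#' @param cz converged vertex position.
#' @param fid the [fiducials] used.
#' @param iterations Cz refinement iterations.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(system, positions, cz, fid, iterations = NA_integer_) {
  structure(list(system = system, positions = positions, cz = cz,
                 fiducials = fid, iterations = iterations),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %s, %d labels (Cz converged in %s iterations)\n",
              x$system, nrow(x$positions), x$iterations))
  invisible(x)
}

#' Compute 10-20/10-10/10-5 landmarks on a head surface
#'
#' Refines Cz by iterative bisection, places the sagittal (Nz-Cz-Iz) and
#' coronal (LPA-Cz-RPA) reference rows at the montage fractions, then walks
#' the construction recipe: each entry cuts the head with the plane through
#' three already-placed anchors and subdivides the arc through the middle
#' anchor. Labels placed earlier are never overwritten, which guarantees
#' that nested systems share identical positions.
#'
#' @param mesh closed head [trimesh].
#' @param fid [fiducials].
#' @param system montage system (`"10-10"` default).
#' @param recipe optional custom [montage_recipe] result.
#' @param cz_tol Cz convergence threshold (mesh units).
#' @return a [landmark_set].
#' @export
compute_landmarks <- function(mesh, fid, system = c("10-10", "10-20", "10-5"),
                              recipe = NULL, cz_tol = 1e-6) {
  system <- match.arg(system)
  if (is.null(recipe)) recipe <- montage_recipe(system)
  rc <- refine_cz(mesh, fid, tol = cz_tol)
  pos <- list()
  place <- function(pos, curve, fractions, labels) {
    for (k in seq_along(labels)) {
      if (!is.null(pos[[labels[k]]])) next
      pos[[labels[k]]] <- point_at_fraction(curve, fractions[k])
    }
    pos
  }
  pos <- place(pos, rc$sagittal_arc, recipe$sagittal$fraction, recipe$sagittal$label)
  pos <- place(pos, rc$coronal_arc, recipe$coronal$fraction, recipe$coronal$label)
  for (cv in recipe$curves) {
    anchors <- lapply(cv$anchors, function(a) {
      if (is.null(pos[[a]])) stop("recipe anchor not yet placed: ", a)
      pos[[a]]
    })
    loop <- tryCatch(
      cross_section(mesh, anchors[[1]], anchors[[2]], anchors[[3]]),
      error = function(e) stop("cross-section failed for curve through ",
                               paste(cv$anchors, collapse = "-"), ": ",
                               conditionMessage(e)))
    arc <- arc_on_loop(loop, anchors[[1]], anchors[[3]], via = anchors[[2]])
    pos <- place(pos, arc, cv$fractions, cv$labels)
  }
  if (!is.null(recipe$subset)) pos <- pos[names(pos) %in% recipe$subset]
  mat <- do.call(rbind, pos)
  rownames(mat) <- names(pos)
  landmark_set(system, mat, cz = rc$cz, fid = fid, iterations = rc$iterations)
}

# ----------------------------------------------------------- landmark mesh

#' Triangulate a landmark set into a surface mesh
#'
#' Builds a triangular mesh whose vertices are exactly the landmark positions
#' (labels preserved), by Delaunay triangulation of the positions after
#' stereographic projection of their directions from the head center.
#'
#' @param landmarks a [landmark_set] with at least 4 non-coplanar positions.
#' @return [trimesh] with a `labels` attribute (one label per vertex).
#' @export
landmark_mesh <- function(landmarks) {
  P <- landmarks$positions
  if (nrow(P) < 4L) stop("need at least 4 landmark positions")
  sv <- svd(sweep(P, 2, colMeans(P)))$d
  if (sv[3] < 1e-9 * sv[1]) stop("landmark positions are coplanar")
  frame <- canonical_frame(landmarks$fiducials)
  local <- frame$to_frame(P)
  dirs <- local / sqrt(rowSums(local^2))
  # stereographic projection from the inferior pole
  denom <- 1 + dirs[, 3]
  if (any(denom < 1e-9)) denom[denom < 1e-9] <- 1e-9
  xy <- cbind(dirs[, 1] / denom, dirs[, 2] / denom)
  tri <- delaunay2d(xy)
  mesh <- trimesh(P, tri, validate = TRUE)
  attr(mesh, "labels") <- rownames(P)
  mesh
}

# Bowyer-Watson incremental Delaunay triangulation in 2D.
delaunay2d <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) stop("need >= 3 points")
  rng <- apply(xy, 2, range)
  d <- max(rng[2, ] - rng[1, ], 1e-9)
  mid <- colMeans(rng)
  super <- rbind(mid + c(-20 * d, -10 * d),
                 mid + c(20 * d, -10 * d),
                 mid + c(0, 20 * d))
  pts <- rbind(xy, super)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  circum <- function(t) {
    a <- pts[t[1], ]; b <- pts[t[2], ]; c <- pts[t[3], ]
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
    dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(dd) < 1e-300) return(c(Inf, Inf, Inf))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / dd
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / dd
    r2 <- (ax - ux)^2 + (ay - uy)^2
    c(ux, uy, r2)
  }
  ccache <- list(circum(tris[[1]]))
  for (p in seq_len(n)) {
    px <- xy[p, 1]; py <- xy[p, 2]
    bad <- which(vapply(seq_along(tris), function(i) {
      cc <- ccache[[i]]
      (px - cc[1])^2 + (py - cc[2])^2 <= cc[3] * (1 + 1e-12)
    }, logical(1)))
    # polygon boundary = edges of bad triangles not shared by two bad triangles
    edges <- do.call(rbind, lapply(tris[bad], function(t)
      rbind(t[c(1, 2)], t[c(2, 3)], t[c(3, 1)])))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- !(key %in% key[duplicated(key)])
    boundary <- edges[keep, , drop = FALSE]
    tris <- tris[-bad]
    ccache <- ccache[-bad]
    for (e in seq_len(nrow(boundary))) {
      t <- c(boundary[e, 1], boundary[e, 2], p)
      tris[[length(tris) + 1L]] <- t
      ccache[[length(ccache) + 1L]] <- circum(t)
    }
  }
  keep <- vapply(tris, function(t) all(t <= n), logical(1))
  tri <- do.call(rbind, tris[keep])
  # consistent CCW orientation in the parameter plane
  a <- xy[tri[, 1], , drop = FALSE]
  b <- xy[tri[, 2], , drop = FALSE]
  c2 <- xy[tri[, 3], , drop = FALSE]
  cwise <- (b[, 1] - a[, 1]) * (c2[, 2] - a[, 2]) -
    (b[, 2] - a[, 2]) * (c2[, 1] - a[, 1]) < 0
  tri[cwise, ] <- tri[cwise, c(1, 3, 2)]
  tri
}
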