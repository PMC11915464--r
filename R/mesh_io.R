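#' Volumetric image
#'
#' A 3D scalar or integer-label grid with voxel size and origin metadata.
#' Integer-valued arrays are treated as label maps by the surface extractor.
#'
#' @param array 3D numeric array.
#' @param voxel_size length-3 positive voxel dimensions (mm).
#' @param origin length-3 world position of voxel (1,1,1) (mm).
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(array, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(array)) != 3L) stop("volume must be 3D")
  if (length(array) == 0L) stop("volume array is empty")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers")
  structure(list(array = array, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, %s mm/voxel\n",
              paste(dim(x$array), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

mesh_formats <- c("stl", "off", "obj", "jmesh")

sniff_format <- function(path, format = NULL) {
  if (!is.null(format)) {
    format <- match.arg(tolower(format), mesh_formats)
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = "stl", off = "off", obj = "obj",
         jmsh = "jmesh", jmesh = "jmesh", json = "jmesh",
         stop("cannot infer mesh format from extension '", ext,
              "'; pass `format` explicitly"))
}

#' Read a triangular surface mesh
#'
#' Supports binary and ASCII STL, OFF, OBJ (geometry only) and the plain-array
#' JMesh JSON container. STL stores vertices per facet; they are merged on
#' read by exact coordinate equality only, so topology is never changed
#' silently (use [weld()] for tolerance-based merging).
#'
#' @param path file path.
#' @param format one of `"stl"`, `"off"`, `"obj"`, `"jmesh"`; inferred from the
#'   file extension when `NULL`.
#' @return a [trimesh] (units: mm).
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- sniff_format(path, format)
  switch(format,
         stl = read_stl(path),
         off = read_off(path),
         obj = read_obj(path),
         jmesh = read_jmesh(path))
}

#' Write a triangular surface mesh
#'
#' @param mesh a [trimesh].
#' @param path output path.
#' @param format output format; inferred from the extension when `NULL`.
#' @param binary write binary STL (default) rather than ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = TRUE) {
  stopifnot(inherits(mesh, "trimesh"))
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L)
    stop("refusing to write an empty mesh")
  format <- sniff_format(path, format)
  switch(format,
         stl = write_stl(mesh, path, binary = binary),
         off = write_off(mesh, path),
         obj = write_obj(mesh, path),
         jmesh = write_jmesh(mesh, path))
  invisible(path)
}

# ------------------------------------------------------------------- STL

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  if (length(header) < 80) stop("malformed STL: truncated header (byte ",
                                length(header), ")")
  # ASCII STL starts with "solid" and contains "facet" text; binary may also
  # start with "solid", so check the facet count against the file size.
  is_ascii <- identical(rawToChar(header[1:5]), "solid")
  if (is_ascii) {
    nfacets <- readBin(con, "integer", 1, size = 4, endian = "little")
    expected <- 84 + as.numeric(nfacets) * 50
    if (length(nfacets) == 0 || file.size(path) != expected) {
      close(con); on.exit(NULL)
      return(read_stl_ascii(path))
    }
    seek(con, 84)
  } else {
    nfacets <- readBin(con, "integer", 1, size = 4, endian = "little")
  }
  if (length(nfacets) == 0 || nfacets < 0) stop("malformed STL: bad facet count")
  # facet records are 50 bytes: 12 little-endian floats + 2 attribute bytes
  seek(con, 84)
  raw_all <- readBin(con, "raw", n = nfacets * 50)
  if (length(raw_all) < nfacets * 50)
    stop("malformed STL: truncated facet data")
  m <- matrix(raw_all, nrow = 50)
  coords <- readBin(as.raw(m[1:48, ]), "numeric", n = nfacets * 12, size = 4,
                    endian = "little")
  coords <- matrix(coords, ncol = 12, byrow = TRUE)
  v <- rbind(coords[, 4:6, drop = FALSE], coords[, 7:9, drop = FALSE],
             coords[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3 * nfacets), ncol = 3)))
  v <- v[ord, , drop = FALSE]              # per-facet vertex order v1,v2,v3
  stl_assemble(v)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (!length(vl)) stop("malformed ASCII STL: no vertex lines")
  parts <- strsplit(trimws(vl), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 4L)
  if (length(bad))
    stop("malformed ASCII STL at line containing: ", vl[bad[1]])
  v <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(v)) stop("malformed ASCII STL: non-numeric vertex")
  if (nrow(v) %% 3 != 0) stop("malformed ASCII STL: vertex count not multiple of 3")
  stl_assemble(v)
}

stl_assemble <- function(v) {
  # merge exactly-equal coordinates (STL stores per-facet vertices)
  cl <- cpp_weld_clusters(v, 0) + 1L
  first <- !duplicated(cl)
  verts <- v[first, , drop = FALSE]
  remap <- integer(max(cl))
  remap[cl[first]] <- seq_len(sum(first))
  idx <- remap[cl]
  f <- matrix(idx, ncol = 3, byrow = TRUE)
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  trimesh(verts, f[keep, , drop = FALSE])
}

write_stl <- function(mesh, path, binary = TRUE) {
  tc <- tri_corners(mesh)
  n <- cross_rows(tc$b - tc$a, tc$c - tc$a)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  nf <- nrow(mesh$faces)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("%-80s", "capforge binary STL (mm)")), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    block <- matrix(0, 12, nf)
    block[1:3, ] <- t(n)
    block[4:6, ] <- t(tc$a)
    block[7:9, ] <- t(tc$b)
    block[10:12, ] <- t(tc$c)
    flt <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
    fm <- matrix(flt, nrow = 48)
    out <- rbind(fm, matrix(as.raw(0), 2, nf))
    writeBin(as.vector(out), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid capforge", con)
    for (i in seq_len(nf)) {
      writeLines(c(
        sprintf("facet normal %.9e %.9e %.9e", n[i, 1], n[i, 2], n[i, 3]),
        "  outer loop",
        sprintf("    vertex %.9e %.9e %.9e", tc$a[i, 1], tc$a[i, 2], tc$a[i, 3]),
        sprintf("    vertex %.9e %.9e %.9e", tc$b[i, 1], tc$b[i, 2], tc$b[i, 3]),
        sprintf("    vertex %.9e %.9e %.9e", tc$c[i, 1], tc$c[i, 2], tc$c[i, 3]),
        "  endloop",
        "endfacet"), con)
    }
    writeLines("endsolid capforge", con)
  }
}

# ------------------------------------------------------------------- OFF

read_off <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt) & nzchar(trimws(txt))]
  if (!length(txt) || trimws(txt[1]) != "OFF")
    stop("malformed OFF: missing OFF header (line 1)")
  counts <- as.integer(strsplit(trimws(txt[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  if (anyNA(c(nv, nf))) stop("malformed OFF: bad counts (line 2)")
  vlines <- txt[2 + seq_len(nv)]
  v <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                function(p) as.numeric(p[1:3]), numeric(3)))
  flines <- txt[2 + nv + seq_len(nf)]
  f <- t(vapply(strsplit(trimws(flines), "\\s+"), function(p) {
    k <- as.integer(p[1])
    if (is.na(k) || k != 3L) stop("malformed OFF: only triangles supported")
    as.integer(p[2:4])
  }, integer(3)))
  trimesh(v, f + 1L)   # OFF is 0-indexed
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

# ------------------------------------------------------------------- OBJ

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", txt, value = TRUE)
  flines <- grep("^f\\s", txt, value = TRUE)
  if (!length(vlines)) stop("malformed OBJ: no vertex lines")
  v <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(v)) stop("malformed OBJ: non-numeric vertex")
  f <- t(vapply(strsplit(trimws(flines), "\\s+"), function(p) {
    if (length(p) != 4L) stop("malformed OBJ: only triangular faces supported")
    idx <- vapply(strsplit(p[2:4], "/"), function(q) as.integer(q[1]), 1L)
    idx
  }, integer(3)))
  trimesh(v, f)        # OBJ is 1-indexed
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# capforge OBJ (mm)", con)
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

# ----------------------------------------------------------------- JMesh
# plain-array JMesh dialect: MeshVert = n x 3 numbers, MeshTri = m x 3
# 1-based indices, both as JSON arrays of arrays.

read_jmesh <- function(path) {
  js <- tryCatch(jsonlite::fromJSON(path),
                 error = function(e) stop("malformed JMesh JSON: ",
                                          conditionMessage(e)))
  if (is.null(js$MeshVert) || is.null(js$MeshTri))
    stop("JMesh file lacks MeshVert/MeshTri keys")
  v <- matrix(as.numeric(as.matrix(js$MeshVert)), ncol = 3)
  fm <- as.matrix(js$MeshTri)
  f <- matrix(as.integer(fm[, 1:3]), ncol = 3)
  trimesh(v, f)
}

write_jmesh <- function(mesh, path) {
  payload <- list(
    `_DataInfo_` = list(JMeshVersion = "0.5", Comment = "capforge surface mesh (mm)"),
    MeshVert = unname(mesh$vertices),
    MeshTri = unname(mesh$faces)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
}

# ----------------------------------------------------------------- NIfTI

#' Read a NIfTI volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return a [volume_image]; voxel sizes come from the header, integer arrays
#'   are kept as label maps.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot parse NIfTI header: ",
                                           conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L)
    stop("only 3D volumes are supported (got ", length(dim(arr)), "D)")
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  voxel <- abs(pd[1:3])
  voxel[voxel == 0] <- 1
  volume_image(arr, voxel_size = voxel, origin = c(0, 0, 0))
}

#' Write a volume as NIfTI
#'
#' @param volume a [volume_image].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  img <- RNifti::asNifti(volume$array)
  RNifti::pixdim(img) <- volume$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
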