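# Triangle-mesh container, normals, and PLY/STL I/O.

#' Construct a surface mesh
#'
#' Triangle mesh in physical millimetre coordinates (same frame as the
#' source volume).
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param normals optional n x 3 matrix of per-vertex unit normals; computed
#'   from the faces when omitted.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as_points(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  nv <- nrow(vertices)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nv))
    stop("face indices out of range [1, ", nv, "]")
  mesh <- structure(list(vertices = vertices, faces = faces, normals = NULL),
                    class = "surface_mesh")
  mesh$normals <- if (is.null(normals)) mesh_vertex_normals(mesh)
                  else as_points(normals)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox x [%.1f, %.1f], y [%.1f, %.1f], z [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

face_normals_area <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # 2 * area * unit normal
}

#' Per-vertex normals
#'
#' Area-weighted average of incident face normals, normalised. Face winding
#' determines orientation (outward for meshes produced by
#' [extract_isosurface()]).
#'
#' @param mesh a [surface_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
mesh_vertex_normals <- function(mesh) {
  nv <- nrow(mesh$vertices)
  fn <- face_normals_area(mesh)
  idx <- as.vector(mesh$faces)
  acc <- rowsum(rbind(fn, fn, fn), group = idx, reorder = FALSE)
  out <- matrix(0, nv, 3)
  out[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(out^2))
  len[len == 0] <- 1
  out / len
}

#' Apply a rigid transform to a mesh
#'
#' Vertices and normals are transformed; for improper (reflecting)
#' transforms the face winding is flipped so normals stay outward.
#'
#' @param mesh a [surface_mesh()].
#' @param transform a [rigid_transform()].
#' @return The transformed `surface_mesh`.
#' @export
transform_mesh <- function(mesh, transform) {
  V <- apply_rigid(transform, mesh$vertices)
  F <- mesh$faces
  if (!transform$proper) F <- F[, c(1, 3, 2), drop = FALSE]
  surface_mesh(V, F)
}

mesh_centroid <- function(mesh) colMeans(mesh$vertices)

# ---- PLY ---------------------------------------------------------------

#' Read or write meshes in PLY/STL format
#'
#' `write_mesh()` dispatches on the file extension (`.ply` or `.stl`);
#' `read_mesh()` likewise. PLY files carry shared-vertex topology and
#' per-vertex normals; STL triangles are welded on exact coordinates when
#' read back.
#'
#' @param mesh a [surface_mesh()].
#' @param path file path ending in `.ply` or `.stl`.
#' @param binary logical; write binary (default) or ASCII.
#' @return `write_mesh()` returns `path` invisibly; `read_mesh()` returns a
#'   [surface_mesh()].
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  lower <- tolower(path)
  if (grepl("\\.ply$", lower)) write_ply(mesh, path, binary)
  else if (grepl("\\.stl$", lower)) write_stl(mesh, path, binary)
  else stop("unsupported mesh format (use .ply or .stl): ", path)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.ply$", lower)) return(read_ply(path))
  if (grepl("\\.stl$", lower)) return(read_stl(path))
  stop("unsupported mesh format (use .ply or .stl): ", path)
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  fmt <- if (binary) "binary_little_endian 1.0" else "ascii 1.0"
  hdr <- c("ply", paste("format", fmt), "comment pelvinc mesh",
           paste("element vertex", nv),
           "property float x", "property float y", "property float z",
           "property float nx", "property float ny", "property float nz",
           paste("element face", nf),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  VN <- cbind(mesh$vertices, mesh$normals)
  if (binary) {
    writeBin(as.numeric(t(VN)), con, size = 4, endian = "little")
    if (nf > 0) {
      # interleave uchar count with 3 int32 indices
      F0 <- t(mesh$faces) - 1L
      for (i in seq_len(nf)) {
        writeBin(as.raw(3), con)
        writeBin(as.integer(F0[, i]), con, size = 4, endian = "little")
      }
    }
  } else {
    vtxt <- apply(VN, 1, function(r) paste(format(r, digits = 9), collapse = " "))
    ftxt <- apply(mesh$faces - 1L, 1, function(r) paste(c(3, r), collapse = " "))
    writeBin(charToRaw(paste0(paste(c(vtxt, ftxt), collapse = "\n"), "\n")), con)
  }
  invisible(path)
}

read_ply <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  # locate "end_header\n" at the byte level (the body may contain NULs)
  pat <- charToRaw("end_header\n")
  limit <- min(length(bytes), 65536)
  hdr_end <- -1L
  for (at in seq_len(limit - length(pat) + 1L)) {
    if (bytes[at] == pat[1] &&
        identical(bytes[at:(at + length(pat) - 1L)], pat)) {
      hdr_end <- at
      break
    }
  }
  if (hdr_end < 0) stop("PLY header not found in ", path)
  data_at <- hdr_end + length(pat)
  hdr <- strsplit(rawToChar(bytes[seq_len(hdr_end - 1L)]), "\r?\n")[[1]]
  fmt <- sub("^format\\s+", "", grep("^format", hdr, value = TRUE)[1])
  binary <- grepl("binary_little_endian", fmt)
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", hdr, value = TRUE)[1]))
  # vertex property names in order
  vprops <- character(0)
  in_vertex <- FALSE
  for (ln in hdr) {
    if (grepl("^element vertex", ln)) { in_vertex <- TRUE; next }
    if (grepl("^element", ln)) in_vertex <- FALSE
    if (in_vertex && grepl("^property float", ln))
      vprops <- c(vprops, sub("^property float\\s+", "", ln))
  }
  np <- length(vprops)
  if (np < 3) stop("PLY vertex element must have at least x, y, z")
  if (binary) {
    con <- rawConnection(bytes[data_at:length(bytes)])
    on.exit(close(con))
    vals <- readBin(con, "numeric", nv * np, size = 4, endian = "little")
    VN <- matrix(vals, ncol = np, byrow = TRUE)
    Fm <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      if (cnt != 3) stop("only triangle faces supported, got ", cnt)
      Fm[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little")
    }
  } else {
    lines <- strsplit(rawToChar(bytes[data_at:length(bytes)]), "\r?\n")[[1]]
    VN <- do.call(rbind, lapply(lines[seq_len(nv)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    Fm <- do.call(rbind, lapply(lines[nv + seq_len(nf)], function(l) {
      v <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
      if (v[1] != 3) stop("only triangle faces supported")
      v[2:4]
    }))
    if (nf == 0) Fm <- matrix(integer(0), 0, 3)
  }
  ix <- match(c("x", "y", "z"), vprops)
  V <- VN[, ix, drop = FALSE]
  N <- if (all(c("nx", "ny", "nz") %in% vprops))
    VN[, match(c("nx", "ny", "nz"), vprops), drop = FALSE] else NULL
  surface_mesh(V, Fm + 1L, normals = N)
}

# ---- STL ---------------------------------------------------------------

write_stl <- function(mesh, path, binary = TRUE) {
  V <- mesh$vertices
  F <- mesh$faces
  nf <- nrow(F)
  fn <- face_normals_area(mesh)
  len <- sqrt(rowSums(fn^2)); len[len == 0] <- 1
  fn <- fn / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "pelvinc binary STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    tri <- t(cbind(fn, V[F[, 1], ], V[F[, 2], ], V[F[, 3], ]))
    for (i in seq_len(nf)) {
      writeBin(as.numeric(tri[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid pelvinc", con)
    for (i in seq_len(nf)) {
      writeLines(sprintf("facet normal %g %g %g", fn[i, 1], fn[i, 2], fn[i, 3]), con)
      writeLines("  outer loop", con)
      for (k in 1:3) {
        v <- V[F[i, k], ]
        writeLines(sprintf("    vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
      }
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid pelvinc", con)
  }
  invisible(path)
}

read_stl <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  is_ascii <- identical(rawToChar(bytes[1:5]), "solid") &&
    !any(bytes[1:min(512, length(bytes))] == as.raw(0))
  if (is_ascii) {
    lines <- strsplit(rawToChar(bytes), "\r?\n")[[1]]
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(vl, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4])))
  } else {
    con <- rawConnection(bytes)
    on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    rec <- readBin(con, "raw", nf * 50)
    recm <- matrix(rec, nrow = 50)
    fl <- matrix(readBin(as.raw(recm[1:48, ]), "numeric", nf * 12, size = 4,
                         endian = "little"), ncol = 12, byrow = TRUE)
    coords <- matrix(t(fl[, 4:12, drop = FALSE]), ncol = 3, byrow = TRUE)
  }
  # weld on exact coordinates
  key <- paste(coords[, 1], coords[, 2], coords[, 3], sep = "_")
  uk <- !duplicated(key)
  V <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  Fm <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(V, Fm)
}
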