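# Canonical HU volume container and research-format I/O (NIfTI-1, NRRD).
#
# Physical convention: LPS (DICOM native), voxel indices 0-based, physical
# points are voxel centers:  p = origin + direction %*% (spacing * ijk).
# NIfTI stores RAS affines; rows x/y are negated on read and write.

#' Construct a CT volume
#'
#' Canonical container for a HU-calibrated CT volume with physical geometry.
#'
#' @param voxels 3-d numeric array of Hounsfield units.
#' @param spacing length-3 positive numeric, voxel spacing in mm.
#' @param origin length-3 numeric, physical position (mm, LPS) of voxel
#'   `(0, 0, 0)`.
#' @param direction 3x3 orthonormal direction-cosine matrix (columns are the
#'   physical directions of the voxel axes).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0), direction = diag(3)) {
  if (length(dim(voxels)) != 3)
    stop("voxels must be a 3-d array (got ", length(dim(voxels)), " dims)")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  stopifnot(length(spacing) == 3, length(origin) == 3,
            all(dim(direction) == c(3, 3)))
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (abs(abs(det(direction)) - 1) > 1e-6 ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction matrix is not orthonormal")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%.1f, %.1f, %.1f) mm\n",
              min(x$voxels), max(x$voxels),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# index->physical 3x3 matrix (direction * diag(spacing))
vol_matrix <- function(vol) vol$direction %*% diag(vol$spacing)

#' Map voxel indices to physical points
#'
#' @param vol a [ct_volume()].
#' @param ijk 0-based voxel indices, length-3 vector or n x 3 matrix
#'   (may be fractional).
#' @return Physical points (mm, LPS) with the same shape as `ijk`.
#' @export
voxel_to_physical <- function(vol, ijk) {
  single <- is.null(dim(ijk))
  P <- as_points(ijk) %*% t(vol_matrix(vol))
  P <- sweep(P, 2, vol$origin, `+`)
  if (single) as.numeric(P) else P
}

#' Map physical points to voxel indices
#'
#' Inverse of [voxel_to_physical()]; returns fractional 0-based indices.
#'
#' @inheritParams voxel_to_physical
#' @param points physical points (mm), length-3 vector or n x 3 matrix.
#' @return 0-based (fractional) voxel indices.
#' @export
physical_to_voxel <- function(vol, points) {
  single <- is.null(dim(points))
  P <- sweep(as_points(points), 2, vol$origin, `-`)
  I <- P %*% t(solve(vol_matrix(vol)))
  if (single) as.numeric(I) else I
}

#' Read a volume from NIfTI or NRRD
#'
#' Reads `.nii`, `.nii.gz` or `.nrrd` into the canonical LPS [ct_volume()].
#' NIfTI affines (RAS) are converted to LPS.
#'
#' @param path file path.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return(read_nifti(path))
  if (grepl("\\.nrrd$", lower)) return(read_nrrd(path))
  stop("unsupported volume format: '",
       sub("^.*(\\.[A-Za-z.]+)$", "\\1", path),
       "' (supported: .nii, .nii.gz, .nrrd)")
}

#' Write a volume to NIfTI or NRRD
#'
#' @param vol a [ct_volume()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) write_nifti(vol, path)
  else if (grepl("\\.nrrd$", lower)) write_nrrd(vol, path)
  else stop("unsupported volume format: '",
            sub("^.*(\\.[A-Za-z.]+)$", "\\1", path), "'")
  invisible(path)
}

# ---- NIfTI-1 -----------------------------------------------------------

ras_flip <- diag(c(-1, -1, 1))

write_nifti <- function(vol, path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- dim(vol$voxels)
  wi16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wi32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wraw <- function(nbytes) writeBin(raw(nbytes), con)

  A <- ras_flip %*% vol_matrix(vol)           # RAS affine, 3x3 part
  o <- as.numeric(ras_flip %*% vol$origin)

  wi32(348)                    # sizeof_hdr
  wraw(10); wraw(18)           # data_type, db_name
  wi32(0); wi16(0); wraw(2)    # extents, session_error, regular+dim_info
  wi16(c(3, d, 1, 1, 1, 1))    # dim[8]
  wf32(c(0, 0, 0)); wi16(0)    # intent_p1..3, intent_code
  wi16(64); wi16(64); wi16(0)  # datatype float64, bitpix, slice_start
  wf32(c(1, vol$spacing, 1, 1, 1, 1))  # pixdim[8]
  wf32(352); wf32(1); wf32(0)  # vox_offset, scl_slope, scl_inter
  wi16(0); wraw(2)             # slice_end, slice_code+xyzt_units
  wf32(c(0, 0, 0, 0))          # cal_max, cal_min, slice_duration, toffset
  wi32(c(0, 0))                # glmax, glmin
  wraw(80); wraw(24)           # descrip, aux_file
  wi16(0); wi16(1)             # qform_code, sform_code
  wf32(c(0, 0, 0, 0, 0, 0))    # quatern b,c,d + qoffset x,y,z
  wf32(c(A[1, ], o[1]))        # srow_x
  wf32(c(A[2, ], o[2]))        # srow_y
  wf32(c(A[3, ], o[3]))        # srow_z
  wraw(16)                     # intent_name
  writeBin(charToRaw("n+1"), con); wraw(1)  # magic
  wraw(4)                      # extension flag
  writeBin(as.numeric(vol$voxels), con, size = 8, endian = "little")
  invisible(path)
}

read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri16 <- function(n) readBin(con, "integer", n, size = 2, endian = "little")
  ri32 <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf32 <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")

  sizeof_hdr <- ri32(1)
  if (!identical(sizeof_hdr, 348L))
    stop("not a little-endian NIfTI-1 file (sizeof_hdr = ", sizeof_hdr, ")")
  readBin(con, "raw", 10 + 18 + 4 + 2 + 2)
  dims <- ri16(8)
  ndim <- dims[1]
  if (ndim < 3 || any(dims[5:8] > 1))
    stop("expected a 3-d volume, got dim = (", paste(dims[2:(1 + max(ndim, 1))],
         collapse = ", "), ")")
  d <- dims[2:4]
  rf32(3); ri16(1)
  datatype <- ri16(1); ri16(1); ri16(1)      # datatype, bitpix, slice_start
  pixdim <- rf32(8)
  vox_offset <- rf32(1)
  scl_slope <- rf32(1); scl_inter <- rf32(1)
  ri16(1); readBin(con, "raw", 2)
  rf32(4); ri32(2)
  readBin(con, "raw", 80 + 24)
  qform_code <- ri16(1); sform_code <- ri16(1)
  quat <- rf32(6)
  srow <- matrix(rf32(12), nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16)
  magic <- rawToChar(readBin(con, "raw", 4)[1:3])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic: ", magic)

  # affine (RAS)
  if (sform_code > 0) {
    A <- srow[, 1:3]
    o <- srow[, 4]
  } else if (qform_code > 0) {
    b <- quat[1]; cq <- quat[2]; dq <- quat[3]
    a2 <- 1 - b^2 - cq^2 - dq^2
    a <- sqrt(max(a2, 0))
    Rm <- matrix(c(
      a^2 + b^2 - cq^2 - dq^2, 2 * (b * cq - a * dq), 2 * (b * dq + a * cq),
      2 * (b * cq + a * dq), a^2 + cq^2 - b^2 - dq^2, 2 * (cq * dq - a * b),
      2 * (b * dq - a * cq), 2 * (cq * dq + a * b), a^2 + dq^2 - b^2 - cq^2),
      3, 3)
    qfac <- if (pixdim[1] < 0) -1 else 1
    A <- Rm %*% diag(c(pixdim[2:3], qfac * pixdim[4]))
    o <- quat[4:6]
  } else {
    A <- diag(pixdim[2:4])
    o <- c(0, 0, 0)
  }

  # 348 header bytes have been consumed; skip to vox_offset by reading
  # (seek() is unreliable on gz connections)
  nskip <- round(vox_offset) - 348L
  if (nskip > 0) readBin(con, "raw", nskip)
  n <- prod(d)
  vox <- switch(as.character(datatype),
    "2"   = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4"   = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "8"   = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    "16"  = readBin(con, "numeric", n, size = 4, endian = "little"),
    "64"  = readBin(con, "numeric", n, size = 8, endian = "little"),
    "512" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                               endian = "little")),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (length(vox) != n) stop("truncated NIfTI data")
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vox <- vox * scl_slope + scl_inter

  # RAS -> LPS
  A <- ras_flip %*% A
  o <- as.numeric(ras_flip %*% o)
  spacing <- sqrt(colSums(A^2))
  direction <- A %*% diag(1 / spacing)
  ct_volume(array(vox, dim = d), spacing = spacing, origin = o,
            direction = direction)
}

# ---- NRRD (attached raw, LPS space) ------------------------------------

write_nrrd <- function(vol, path) {
  A <- vol_matrix(vol)
  dirs <- apply(A, 2, function(col) sprintf("(%.17g,%.17g,%.17g)",
                                            col[1], col[2], col[3]))
  hdr <- c(
    "NRRD0004",
    "# produced by pelvinc",
    "type: double",
    "dimension: 3",
    paste("sizes:", paste(dim(vol$voxels), collapse = " ")),
    "space: left-posterior-superior",
    paste("space directions:", paste(dirs, collapse = " ")),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    "endian: little",
    "encoding: raw",
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(as.numeric(vol$voxels), con, size = 8, endian = "little")
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # read header bytes up to the blank line
  hdr_raw <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) stop("truncated NRRD header")
    hdr_raw <- c(hdr_raw, b)
    n <- length(hdr_raw)
    if (n >= 2 && hdr_raw[n] == as.raw(10) && hdr_raw[n - 1] == as.raw(10)) break
  }
  lines <- strsplit(rawToChar(hdr_raw), "\n")[[1]]
  if (!grepl("^NRRD", lines[1])) stop("not an NRRD file")
  fields <- list()
  for (ln in lines[-1]) {
    if (grepl("^#", ln) || !nzchar(ln)) next
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1]]
    if (length(kv) == 2)
      fields[[tolower(trimws(kv[1]))]] <- trimws(sub("^=?\\s*", "", kv[2]))
  }
  if (!identical(fields[["dimension"]], "3"))
    stop("expected a 3-d NRRD, got dimension ", fields[["dimension"]])
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (!identical(tolower(fields[["encoding"]]), "raw"))
    stop("only raw NRRD encoding is supported")
  parse_vec <- function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  dirs_s <- regmatches(fields[["space directions"]],
                       gregexpr("\\([^)]*\\)", fields[["space directions"]]))[[1]]
  A <- sapply(dirs_s, parse_vec)
  origin <- if (!is.null(fields[["space origin"]]))
    parse_vec(fields[["space origin"]]) else c(0, 0, 0)
  space <- tolower(fields[["space"]] %||% "left-posterior-superior")
  flips <- switch(space,
    "left-posterior-superior" = c(1, 1, 1),
    "right-anterior-superior" = c(-1, -1, 1),
    stop("unsupported NRRD space: ", space))
  A <- diag(flips) %*% A
  origin <- flips * origin
  type <- tolower(fields[["type"]])
  n <- prod(sizes)
  endian <- tolower(fields[["endian"]] %||% "little")
  vox <- switch(type,
    "double" = , "float64" = readBin(con, "numeric", n, size = 8, endian = endian),
    "float" = , "float32" = readBin(con, "numeric", n, size = 4, endian = endian),
    "short" = , "int16" = as.numeric(readBin(con, "integer", n, size = 2,
                                             endian = endian)),
    "int" = , "int32" = as.numeric(readBin(con, "integer", n, size = 4,
                                           endian = endian)),
    "uchar" = , "uint8" = as.numeric(readBin(con, "integer", n, size = 1,
                                             signed = FALSE)),
    stop("unsupported NRRD type: ", type))
  if (length(vox) != n) stop("truncated NRRD data")
  spacing <- sqrt(colSums(A^2))
  direction <- A %*% diag(1 / spacing)
  ct_volume(array(vox, dim = sizes), spacing = spacing, origin = origin,
            direction = direction)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crop a volume to its foreground bounding box
#'
#' Trims the grid to the axis-aligned bounding box of voxels above
#' `hu_low`, plus a padding margin. Useful after [resample_volume_rigid()],
#' whose rotated field of view is mostly background.
#'
#' @param vol a [ct_volume()].
#' @param hu_low foreground threshold (HU, default -500).
#' @param pad padding in voxels (default 4).
#' @return The cropped [ct_volume()].
#' @export
crop_volume <- function(vol, hu_low = -500, pad = 4L) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$voxels)
  fg <- vol$voxels > hu_low
  if (!any(fg)) stop("no voxels above ", hu_low, " HU; nothing to crop to")
  rng <- lapply(1:3, function(ax) {
    any_ax <- apply(fg, ax, any)
    range(which(any_ax))
  })
  lo <- pmax(1L, vapply(rng, `[`, 0L, 1) - pad)
  hi <- pmin(d, vapply(rng, `[`, 0L, 2) + pad)
  sub <- vol$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ct_volume(sub, spacing = vol$spacing,
            origin = voxel_to_physical(vol, lo - 1L),
            direction = vol$direction)
}

# ---- resampling --------------------------------------------------------

#' Rigidly move and resample a volume
#'
#' Applies a rigid transform to the physical content of a volume and
#' resamples it by trilinear interpolation onto a new axis-aligned grid
#' covering the transformed field of view. Used by the pose-invariance
#' checks of the pipeline.
#'
#' @param vol a [ct_volume()].
#' @param transform a [rigid_transform()] moving physical points.
#' @param spacing spacing of the output grid (defaults to the input spacing).
#' @param outside value assigned outside the source field of view (defaults
#'   to the minimum voxel value, i.e. background HU).
#' @return A [ct_volume()] with identity orientation.
#' @export
resample_volume_rigid <- function(vol, transform, spacing = vol$spacing,
                                  outside = min(vol$voxels)) {
  stopifnot(inherits(vol, "ct_volume"), inherits(transform, "rigid_transform"))
  d <- dim(vol$voxels)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  pc <- apply_rigid(transform, voxel_to_physical(vol, corners))
  lo <- apply(pc, 2, min)
  hi <- apply(pc, 2, max)
  nd <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  # source index = Minv (Rinv (diag(spacing) ijk + lo) + tinv - origin)
  inv <- invert_rigid(transform)
  Minv <- solve(vol_matrix(vol))
  A <- Minv %*% inv$rotation %*% diag(spacing)
  b <- as.numeric(Minv %*% (inv$rotation %*% lo + inv$translation - vol$origin))
  vals <- .resample_affine(as.numeric(vol$voxels), dim(vol$voxels), nd,
                           A, b, outside)
  ct_volume(array(vals, dim = nd), spacing = spacing, origin = lo)
}
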