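# Minimal DICOM series reader (explicit VR little endian, single-frame CT).
#
# Only the attributes needed for geometry and HU calibration are parsed.
# Slices are sorted by spatial position along the slice normal, never by
# file name; the inter-slice gap must be uniform to 1%.

dcm_tag <- function(group, elem) bitwShiftL(group, 16) + elem

DCM_TAGS <- list(
  transfer_syntax   = dcm_tag(0x0002, 0x0010),
  series_uid        = dcm_tag(0x0020, 0x000E),
  ipp               = dcm_tag(0x0020, 0x0032),
  iop               = dcm_tag(0x0020, 0x0037),
  rows              = dcm_tag(0x0028, 0x0010),
  cols              = dcm_tag(0x0028, 0x0011),
  pixel_spacing     = dcm_tag(0x0028, 0x0030),
  bits_allocated    = dcm_tag(0x0028, 0x0100),
  pixel_rep         = dcm_tag(0x0028, 0x0103),
  rescale_intercept = dcm_tag(0x0028, 0x1052),
  rescale_slope     = dcm_tag(0x0028, 0x1053),
  pixel_data        = dcm_tag(0x7FE0, 0x0010)
)

# parse one explicit-VR little-endian file into a tag -> raw-value list
parse_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 136 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  n <- length(bytes)
  u16 <- function(at) readBin(bytes[at:(at + 1)], "integer", size = 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(bytes[at:(at + 3)], "integer", size = 4,
                              endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elements <- list()
  ts_checked <- FALSE
  while (pos + 7 <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      val_at <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      val_at <- pos + 8L
    }
    if (len < 0) stop("undefined-length element unsupported at tag (",
                      sprintf("%04X,%04X", group, elem), ") in ", path)
    key <- as.character(dcm_tag(group, elem))
    val <- if (len > 0) bytes[val_at:(val_at + len - 1L)] else raw(0)
    elements[[key]] <- list(vr = vr, value = val)
    pos <- val_at + len
    if (!ts_checked && group > 0x0002) {
      ts <- dcm_string(elements, DCM_TAGS$transfer_syntax)
      if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
        stop("unsupported transfer syntax '", ts,
             "' (only explicit VR little endian): ", path)
      ts_checked <- TRUE
    }
  }
  elements
}

dcm_string <- function(el, tag) {
  e <- el[[as.character(tag)]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$value[e$value != as.raw(0)]))
}

dcm_numeric <- function(el, tag) {
  s <- dcm_string(el, tag)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_uint16 <- function(el, tag) {
  e <- el[[as.character(tag)]]
  if (is.null(e)) return(NULL)
  readBin(e$value, "integer", size = 2, signed = FALSE, endian = "little")
}

#' Read a DICOM CT series into a volume
#'
#' Reads all files of one single-frame CT series (explicit VR little
#' endian), rescales stored values to Hounsfield units, and sorts slices by
#' spatial position along the slice normal (not by file name).
#'
#' @param directory path to a directory holding exactly one series.
#' @return A [ct_volume()] in LPS coordinates.
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in ", directory)
  slices <- lapply(files, parse_dicom_file)

  uids <- vapply(slices, function(el)
    dcm_string(el, DCM_TAGS$series_uid) %||% "<missing>", "")
  if (length(unique(uids)) > 1)
    stop("directory contains multiple series: ",
         paste(sort(unique(uids)), collapse = ", "))

  first <- slices[[1]]
  iop <- dcm_numeric(first, DCM_TAGS$iop)
  if (is.null(iop) || length(iop) != 6)
    stop("missing ImageOrientationPatient")
  col_dir <- unitv(iop[1:3])
  row_dir <- unitv(iop[4:6])
  normal <- cross3(col_dir, row_dir)

  ipps <- t(vapply(slices, function(el) {
    p <- dcm_numeric(el, DCM_TAGS$ipp)
    if (is.null(p) || length(p) != 3) stop("missing ImagePositionPatient")
    p
  }, numeric(3)))
  z <- as.numeric(ipps %*% normal)
  ord <- order(z)
  slices <- slices[ord]
  ipps <- ipps[ord, , drop = FALSE]
  z <- z[ord]

  nslice <- length(slices)
  if (nslice < 2) stop("need at least 2 slices, got ", nslice)
  gaps <- diff(z)
  gap <- stats::median(gaps)
  bad <- which(abs(gaps - gap) > 0.01 * gap | gaps <= 0)
  if (length(bad) > 0) {
    p <- ipps[bad[1] + 1, ]
    stop(sprintf(paste0("non-uniform or duplicated slice spacing at position ",
                        "(%.4g, %.4g, %.4g): gap %.6g vs median %.6g mm"),
                 p[1], p[2], p[3], gaps[bad[1]], gap))
  }

  px <- dcm_numeric(first, DCM_TAGS$pixel_spacing)  # (row, col) spacing
  if (is.null(px) || length(px) != 2) stop("missing PixelSpacing")
  nrows <- dcm_uint16(first, DCM_TAGS$rows)
  ncols <- dcm_uint16(first, DCM_TAGS$cols)
  bits <- dcm_uint16(first, DCM_TAGS$bits_allocated) %||% 16L
  if (bits != 16) stop("only 16-bit pixel data supported, got ", bits)
  signed <- identical(dcm_uint16(first, DCM_TAGS$pixel_rep), 1L)

  vox <- array(0, dim = c(ncols, nrows, nslice))
  for (s in seq_len(nslice)) {
    el <- slices[[s]]
    slope <- dcm_numeric(el, DCM_TAGS$rescale_slope)
    inter <- dcm_numeric(el, DCM_TAGS$rescale_intercept)
    if (is.null(slope) || is.null(inter))
      stop("missing RescaleSlope/RescaleIntercept; cannot convert to HU")
    pd <- el[[as.character(DCM_TAGS$pixel_data)]]
    if (is.null(pd)) stop("missing PixelData")
    vals <- readBin(pd$value, "integer", n = nrows * ncols, size = 2,
                    signed = signed, endian = "little")
    if (!signed && any(vals < 0)) vals <- vals + 65536 * (vals < 0)
    vox[, , s] <- vals * slope + inter
  }

  ct_volume(vox,
            spacing = c(px[2], px[1], gap),
            origin = ipps[1, ],
            direction = cbind(col_dir, row_dir, normal))
}
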