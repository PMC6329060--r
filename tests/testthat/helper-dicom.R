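# Minimal explicit-VR little-endian DICOM writer for test fixtures.
# Values are padded to even length (UI with NUL, others with space).

dcm_element <- function(group, elem, vr, value_raw) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
  writeBin(charToRaw(vr), con)
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    writeBin(raw(2), con)
    writeBin(as.integer(length(value_raw)), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(length(value_raw)), con, size = 2, endian = "little")
  }
  writeBin(value_raw, con)
  rawConnectionValue(con)
}

dcm_str <- function(s, pad = as.raw(0x20)) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, pad)
  r
}

dcm_us <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

write_dicom_slice <- function(path, pixels, ipp,
                              iop = c(1, 0, 0, 0, 1, 0),
                              pixel_spacing = c(1, 1),   # (row, col)
                              slope = 1, intercept = -1024,
                              series_uid = "1.2.3.4",
                              signed = FALSE,
                              include_rescale = TRUE) {
  ncols <- nrow(pixels)   # first array index = column index (x)
  nrows <- ncol(pixels)
  px <- writeBin(as.integer(as.vector(pixels)), raw(), size = 2,
                 endian = "little")
  body <- c(
    dcm_element(0x0008, 0x0018, "UI", dcm_str(paste0(series_uid, ".",
               paste(round(ipp), collapse = ".")), as.raw(0))),
    dcm_element(0x0020, 0x000E, "UI", dcm_str(series_uid, as.raw(0))),
    dcm_element(0x0020, 0x0032, "DS",
                dcm_str(paste(sprintf("%.8g", ipp), collapse = "\\"))),
    dcm_element(0x0020, 0x0037, "DS",
                dcm_str(paste(sprintf("%.8g", iop), collapse = "\\"))),
    dcm_element(0x0028, 0x0010, "US", dcm_us(nrows)),
    dcm_element(0x0028, 0x0011, "US", dcm_us(ncols)),
    dcm_element(0x0028, 0x0030, "DS",
                dcm_str(paste(sprintf("%.8g", pixel_spacing), collapse = "\\"))),
    dcm_element(0x0028, 0x0100, "US", dcm_us(16)),
    dcm_element(0x0028, 0x0103, "US", dcm_us(if (signed) 1 else 0)))
  if (include_rescale) {
    body <- c(body,
      dcm_element(0x0028, 0x1052, "DS", dcm_str(sprintf("%.8g", intercept))),
      dcm_element(0x0028, 0x1053, "DS", dcm_str(sprintf("%.8g", slope))))
  }
  body <- c(body, dcm_element(0x7FE0, 0x0010, "OW", px))
  meta <- dcm_element(0x0002, 0x0010, "UI",
                      dcm_str("1.2.840.10008.1.2.1", as.raw(0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(path)
}

# write an n-slice axial series holding `stored + intercept*0` raw values
write_test_series <- function(dir, nslice = 10, nx = 12, ny = 10,
                              stored_fun = function(s) matrix(1024L, nx, ny),
                              z0 = 0, dz = 2, shuffle_names = FALSE, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  order_idx <- if (shuffle_names) sample(nslice) else seq_len(nslice)
  for (s in seq_len(nslice)) {
    fname <- file.path(dir, sprintf("slice_%03d.dcm", order_idx[s]))
    write_dicom_slice(fname, stored_fun(s), ipp = c(-10, -20, z0 + (s - 1) * dz),
                      ...)
  }
  invisible(dir)
}
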