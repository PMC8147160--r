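## Minimal DICOM series reader.
##
## Supports the subset of DICOM needed to ingest an uncompressed CT/MR
## series: explicit-VR little-endian transfer syntax, single-frame scalar
## images, 8/16-bit integer pixel data.  Slices are sorted by
## ImagePositionPatient along the slice normal (InstanceNumber as fallback)
## and RescaleSlope/RescaleIntercept are applied, so CT series come back in
## Hounsfield units.  NIfTI remains the canonical interchange format;
## DICOM support is read-only.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

## VRs whose length field is 4 bytes after a 2-byte reserved gap
DICOM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

read_dicom_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", 132L)
  if (length(preamble) < 132L ||
      rawToChar(preamble[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  elems <- list()
  repeat {
    hdr <- readBin(con, "raw", 4L)
    if (length(hdr) < 4L) break
    group <- readBin(hdr[1:2], "integer", size = 2, signed = FALSE,
                     endian = "little")
    element <- readBin(hdr[3:4], "integer", size = 2, signed = FALSE,
                       endian = "little")
    vr <- rawToChar(readBin(con, "raw", 2L))
    if (vr %in% DICOM_LONG_VRS) {
      readBin(con, "raw", 2L) # reserved
      len <- readBin(con, "integer", size = 4, endian = "little")
    } else {
      len <- readBin(con, "integer", size = 2, signed = FALSE,
                     endian = "little")
    }
    if (len < 0) stop("undefined-length element unsupported (tag ",
                      dcm_tag(group, element), ")", call. = FALSE)
    payload <- readBin(con, "raw", len)
    elems[[dcm_tag(group, element)]] <- list(vr = vr, bytes = payload)
    if (group == 0x7FE0 && element == 0x0010) break
  }
  elems
}

dcm_string <- function(elems, tag, default = NULL) {
  e <- elems[[tag]]
  if (is.null(e)) return(default)
  trimws(rawToChar(e$bytes))
}

dcm_numeric <- function(elems, tag, default = NULL) {
  s <- dcm_string(elems, tag)
  if (is.null(s) || !nzchar(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(elems, tag, default = NULL) {
  e <- elems[[tag]]
  if (is.null(e)) return(default)
  readBin(e$bytes, "integer", n = length(e$bytes) %/% 2L, size = 2,
          signed = FALSE, endian = "little")
}

read_dicom_slice <- function(path) {
  el <- read_dicom_file(path)
  rows <- dcm_us(el, dcm_tag(0x0028, 0x0010))
  cols <- dcm_us(el, dcm_tag(0x0028, 0x0011))
  if (is.null(rows) || is.null(cols))
    stop("DICOM file lacks Rows/Columns: ", path, call. = FALSE)
  bits <- dcm_us(el, dcm_tag(0x0028, 0x0100), default = 16L)
  pixrep <- dcm_us(el, dcm_tag(0x0028, 0x0103), default = 0L)
  samples <- dcm_us(el, dcm_tag(0x0028, 0x0002), default = 1L)
  if (samples != 1L)
    stop("non-scalar pixel data (SamplesPerPixel = ", samples, ")",
         call. = FALSE)
  px <- el[[dcm_tag(0x7FE0, 0x0010)]]
  if (is.null(px)) stop("DICOM file lacks PixelData: ", path, call. = FALSE)
  n <- as.integer(rows) * as.integer(cols)
  if (bits == 16L) {
    vals <- readBin(px$bytes, "integer", n = n, size = 2,
                    signed = (pixrep == 1L), endian = "little")
  } else if (bits == 8L) {
    vals <- as.integer(px$bytes[seq_len(n)])
  } else {
    stop("unsupported BitsAllocated: ", bits, call. = FALSE)
  }
  slope <- dcm_numeric(el, dcm_tag(0x0028, 0x1053), default = 1)
  intercept <- dcm_numeric(el, dcm_tag(0x0028, 0x1052), default = 0)
  ## DICOM pixel data is row-major (fastest index = column)
  img <- matrix(vals * slope + intercept, nrow = rows, ncol = cols,
                byrow = TRUE)
  list(
    image = img,
    position = dcm_numeric(el, dcm_tag(0x0020, 0x0032)),
    instance = dcm_numeric(el, dcm_tag(0x0020, 0x0013), default = NA_real_),
    pixel_spacing = dcm_numeric(el, dcm_tag(0x0028, 0x0030),
                                default = c(1, 1)),
    slice_thickness = dcm_numeric(el, dcm_tag(0x0018, 0x0050),
                                  default = NA_real_)
  )
}

read_dicom_series <- function(dir, modality = "CT", units = NULL) {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L)
    files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir,
                                call. = FALSE)
  slices <- lapply(files, read_dicom_slice)
  ## sort by position along the slice normal (z of ImagePositionPatient),
  ## falling back to InstanceNumber
  zpos <- vapply(slices, function(s)
    if (!is.null(s$position) && length(s$position) >= 3) s$position[3]
    else NA_real_, numeric(1))
  if (all(is.finite(zpos))) {
    ord <- order(zpos)
  } else {
    inst <- vapply(slices, function(s) s$instance[1], numeric(1))
    if (anyNA(inst)) stop("DICOM series has neither slice positions nor ",
                          "instance numbers", call. = FALSE)
    ord <- order(inst)
  }
  slices <- slices[ord]
  zpos <- zpos[ord]
  shp <- dim(slices[[1]]$image)
  for (s in slices) if (!identical(dim(s$image), shp))
    stop("inconsistent slice dimensions in DICOM series", call. = FALSE)
  ## slice spacing from positions; must be uniform
  if (length(slices) > 1L && all(is.finite(zpos))) {
    dz <- diff(zpos)
    if (max(dz) - min(dz) > 1e-3 * max(abs(dz)) + 1e-6)
      stop("inconsistent slice spacing in DICOM series", call. = FALSE)
    slice_mm <- abs(dz[1])
  } else {
    slice_mm <- slices[[1]]$slice_thickness
    if (!is.finite(slice_mm)) slice_mm <- 1
  }
  ps <- slices[[1]]$pixel_spacing   # (row spacing, column spacing)
  arr <- array(0, dim = c(length(slices), shp[1], shp[2]))
  for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]$image
  volume(arr, spacing = c(slice_mm, ps[1], ps[2]), modality = modality,
         units = units)
}
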