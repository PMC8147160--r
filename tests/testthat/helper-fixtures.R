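## Shared fixtures, all generated in code.

## small chest phantom used across tests (cached per options)
small_phantom <- function(shape = c(4, 128, 128), noise_sd = 5, seed = 1,
                          preset = "chest",
                          bias = list(type = "gaussian_blobs",
                                      amplitude = 0.3, scale = 40)) {
  make_torso_phantom(phantom_config(preset, shape = shape, bias = bias,
                                    noise_sd = noise_sd, seed = seed))
}

## intensity pairs that encode an exact affine MRI -> HU map
affine_pairs <- function(n, lo, hi, slope = 2, intercept = -100,
                         tissue = 1L) {
  mri <- seq(lo, hi, length.out = n)
  structure(data.frame(mri_au = mri, ct_hu = slope * mri + intercept,
                       tissue = tissue, slice = 1L),
            role = "training",
            class = c("intensity_pair_set", "data.frame"))
}

affine_templates <- function(slope = 2, intercept = -100) {
  list(
    build_template_pair(affine_pairs(25, 20, 120, slope, intercept),
                        "lung"),
    build_template_pair(affine_pairs(25, 120, 220, slope, intercept),
                        "soft_low"),
    build_template_pair(affine_pairs(25, 220, 320, slope, intercept),
                        "soft_high"),
    build_template_pair(affine_pairs(25, 320, 420, slope, intercept),
                        "fat")
  )
}

## ---- minimal explicit-VR little-endian DICOM writer (test oracle) ----

dcm_put <- function(con, group, element, vr, payload) {
  writeBin(as.integer(group), con, size = 2, endian = "little")
  writeBin(as.integer(element), con, size = 2, endian = "little")
  writeChar(vr, con, nchars = 2, eos = NULL)
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
  if (vr %in% long_vrs) {
    writeBin(as.raw(c(0, 0)), con)
    writeBin(length(payload), con, size = 4, endian = "little")
  } else {
    writeBin(length(payload), con, size = 2, endian = "little")
  }
  writeBin(payload, con)
}

dcm_str <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, charToRaw(" "))
  r
}

dcm_us_payload <- function(v) writeBin(as.integer(v), raw(),
                                       size = 2, endian = "little")

## img: matrix of *stored* integer values, laid out [row, col]
write_test_dicom_slice <- function(path, img, z_mm, pixel_spacing = c(1, 1),
                                   slice_thickness = 1, slope = 1,
                                   intercept = 0, instance = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, nchars = 4, eos = NULL)
  dcm_put(con, 0x0008, 0x0060, "CS", dcm_str("CT"))
  dcm_put(con, 0x0018, 0x0050, "DS", dcm_str(format(slice_thickness)))
  dcm_put(con, 0x0020, 0x0013, "IS", dcm_str(format(instance)))
  dcm_put(con, 0x0020, 0x0032, "DS",
          dcm_str(paste(0, 0, format(z_mm), sep = "\\")))
  dcm_put(con, 0x0028, 0x0002, "US", dcm_us_payload(1L))
  dcm_put(con, 0x0028, 0x0010, "US", dcm_us_payload(nrow(img)))
  dcm_put(con, 0x0028, 0x0011, "US", dcm_us_payload(ncol(img)))
  dcm_put(con, 0x0028, 0x0030, "DS",
          dcm_str(paste(format(pixel_spacing[1]), format(pixel_spacing[2]),
                        sep = "\\")))
  dcm_put(con, 0x0028, 0x0100, "US", dcm_us_payload(16L))
  dcm_put(con, 0x0028, 0x0103, "US", dcm_us_payload(0L))
  dcm_put(con, 0x0028, 0x1052, "DS", dcm_str(format(intercept)))
  dcm_put(con, 0x0028, 0x1053, "DS", dcm_str(format(slope)))
  ## row-major pixel order
  vals <- as.integer(t(img))
  dcm_put(con, 0x7FE0, 0x0010, "OW",
          writeBin(vals, raw(), size = 2, endian = "little"))
  invisible(path)
}
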