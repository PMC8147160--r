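registered_phantom <- function(shape = c(10, 96, 96), noise_sd = 0) {
  small_phantom(shape = shape, noise_sd = noise_sd,
                bias = list(type = "none"))
}

test_that("default counts give 25/25/50 pairs per slice, sorted", {
  ph <- registered_phantom()
  pairs <- extract_pairs(ph$mri, ph$ct, ph$labels, slices = c(2, 4, 6, 8))
  expect_equal(nrow(pairs), 4 * (25 + 25 + 50))
  tab <- table(pairs$tissue, pairs$slice)
  expect_true(all(tab["0", ] == 25))
  expect_true(all(tab["1", ] == 50))
  expect_true(all(tab["2", ] == 25))
  ## sorted ascending within each (slice, tissue) group
  for (s in unique(pairs$slice)) for (tt in 0:2) {
    g <- pairs$mri_au[pairs$slice == s & pairs$tissue == tt]
    expect_true(!is.unsorted(g))
  }
})

test_that("rank-based selection covers the range and hits exact ranks", {
  ## linear-ramp slice, mask = all 100 voxels, n = 5 -> 0-based ranks
  ## {0, 24, 49, 74, 99}
  ramp <- volume(array(seq_len(100), c(1, 10, 10)))
  ct <- volume(array(0, c(1, 10, 10)), modality = "CT")
  lab <- tissue_label_map(array(1L, c(1, 10, 10)))
  p <- suppressWarnings(
    extract_pairs(ramp, ct, lab, slices = 1,
                  counts = c(air_lung = 1, soft_tissue = 5, fat = 1)))
  soft <- p[p$tissue == 1L, ]
  expect_equal(soft$mri_au, c(0, 24, 49, 74, 99) + 1)

  ## min and max always selected
  ph <- registered_phantom(shape = c(2, 96, 96), noise_sd = 3)
  pr <- extract_pairs(ph$mri, ph$ct, ph$labels, slices = 1:2)
  for (s in 1:2) for (tt in 0:2) {
    in_mask <- ph$mri$data[s, , ][ph$labels$labels[s, , ] == tt]
    g <- pr$mri_au[pr$slice == s & pr$tissue == tt]
    expect_equal(min(g), min(in_mask))
    expect_equal(max(g), max(in_mask))
  }
})

test_that("small masks are taken whole, with a warning", {
  mri <- volume(array(seq_len(25), c(1, 5, 5)))
  ct <- volume(array(100, c(1, 5, 5)), modality = "CT")
  lab <- tissue_label_map(array(1L, c(1, 5, 5)))
  ## mask of exactly 25 voxels, n = 25: all selected once, sorted
  p <- suppressWarnings(
    extract_pairs(mri, ct, lab, slices = 1,
                  counts = c(air_lung = 1, soft_tissue = 25, fat = 1)))
  soft <- p[p$tissue == 1L, ]
  expect_equal(soft$mri_au, as.numeric(1:25))
  ## fewer voxels than requested: all taken, warning raised (the absent
  ## air/fat classes warn too; keep only the one under test visible)
  suppressWarnings(
    expect_warning(
      extract_pairs(mri, ct, lab, slices = 1,
                    counts = c(air_lung = 1, soft_tissue = 50, fat = 1)),
      "taking all"))
  ## empty class is skipped with a warning
  suppressWarnings(
    expect_warning(
      extract_pairs(mri, ct, lab, slices = 1,
                    counts = c(air_lung = 2, soft_tissue = 5, fat = 2)),
      "empty"))
})

test_that("noiseless phantom pairs lie on the known intensity-HU mapping", {
  ph <- registered_phantom(shape = c(4, 96, 96))
  pairs <- extract_pairs(ph$mri, ph$ct, ph$labels, slices = 1:4)
  lut_mri <- unname(ph$config$tissue_mri_levels)
  lut_hu <- unname(ph$config$tissue_hu_levels)
  expect_equal(pairs$mri_au, lut_mri[pairs$tissue + 1L])
  expect_equal(pairs$ct_hu, lut_hu[pairs$tissue + 1L])
})

test_that("soft-tissue pairs split at the median rank per slice", {
  ph <- registered_phantom(shape = c(4, 96, 96), noise_sd = 3)
  pairs <- extract_pairs(ph$mri, ph$ct, ph$labels, slices = 1:4)
  sp <- split_soft_tissue(pairs)
  expect_equal(nrow(sp$low), 4 * 25)
  expect_equal(nrow(sp$high), 4 * 25)
  for (s in 1:4) {
    lo <- sp$low$mri_au[sp$low$slice == s]
    hi <- sp$high$mri_au[sp$high$slice == s]
    expect_lte(max(lo), min(hi))
  }

  ## odd counts put the extra pair in the low half
  odd <- structure(data.frame(mri_au = c(3, 1, 2), ct_hu = 0:2,
                              tissue = 1L, slice = 1L),
                   class = c("intensity_pair_set", "data.frame"))
  so <- split_soft_tissue(odd)
  expect_equal(nrow(so$low), 2L)
  expect_equal(nrow(so$high), 1L)

  ## ties split by rank, not value
  tied <- structure(data.frame(mri_au = rep(7, 50), ct_hu = 1:50,
                               tissue = 1L, slice = 1L),
                    class = c("intensity_pair_set", "data.frame"))
  st <- split_soft_tissue(tied)
  expect_equal(nrow(st$low), 25L)
  expect_equal(nrow(st$high), 25L)
})

test_that("templates hold one constant block per pair", {
  one <- structure(data.frame(mri_au = 100, ct_hu = 30, tissue = 0L,
                              slice = 1L),
                   class = c("intensity_pair_set", "data.frame"))
  tp1 <- build_template_pair(one, "lung", block_px = 40)
  expect_true(all(tp1$mri_image == 100))
  expect_true(all(tp1$ct_image == 30))

  four <- structure(data.frame(mri_au = c(4, 3, 2, 1) * 10,
                               ct_hu = c(40, 30, 20, 10), tissue = 1L,
                               slice = 1L),
                    class = c("intensity_pair_set", "data.frame"))
  tp <- build_template_pair(four, "soft_low", block_px = 40)
  expect_identical(dim(tp$mri_image), c(80L, 80L))
  ## quadrants constant, MRI ascending row-major
  q <- function(m, r, c) m[(r - 1) * 40 + 1:40, (c - 1) * 40 + 1:40]
  expect_true(all(q(tp$mri_image, 1, 1) == 10))
  expect_true(all(q(tp$mri_image, 1, 2) == 20))
  expect_true(all(q(tp$mri_image, 2, 1) == 30))
  expect_true(all(q(tp$mri_image, 2, 2) == 40))
  ## pixelwise: (mri, ct) is always one of the input pairs
  key <- paste(tp$mri_image, tp$ct_image)
  expect_true(all(key %in% paste(four$mri_au, four$ct_hu)))

  expect_error(build_template_pair(four, "fat", block_px = 10,
                                   grid = c(1, 1)),
               "grid too small")
})

test_that("patch cropping is seeded, centered and label-consistent", {
  tps <- affine_templates()
  ps <- crop_patches(tps, 5, seed = 42)
  expect_identical(dim(ps$inputs), c(20L, 32L, 32L))
  expect_identical(dim(ps$labels), c(20L, 18L, 18L))
  ## same seed twice: identical
  ps2 <- crop_patches(tps, 5, seed = 42)
  expect_identical(ps$inputs, ps2$inputs)
  expect_identical(ps$labels, ps2$labels)
  ## labels obey the affine map encoded in the templates
  expect_equal(ps$labels, array(2 * ps$inputs[, 8:25, 8:25] - 100,
                                dim(ps$labels)))

  ## a 32x32 template forces the single possible crop
  one <- structure(data.frame(mri_au = 5, ct_hu = 7, tissue = 0L,
                              slice = 1L),
                   class = c("intensity_pair_set", "data.frame"))
  tp32 <- build_template_pair(one, "lung", block_px = 32)
  f <- crop_patches(tp32, 3, seed = 1)
  expect_true(all(f$inputs == 5))
  expect_true(all(f$labels == 7))
})

test_that("pairs round-trip through CSV", {
  dir <- withr::local_tempdir()
  ph <- registered_phantom(shape = c(2, 96, 96), noise_sd = 3)
  pairs <- extract_pairs(ph$mri, ph$ct, ph$labels, slices = 1:2)
  p <- file.path(dir, "pairs.csv")
  write_pairs(pairs, p)
  r <- read_pairs(p)
  expect_equal(r$mri_au, pairs$mri_au)
  expect_equal(r$tissue, pairs$tissue)
  expect_equal(attr(r, "role"), "training")
})
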