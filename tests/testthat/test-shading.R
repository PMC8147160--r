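test_that("three-intensity mask is a voxelwise bulk lookup", {
  lab <- tissue_label_map(matrix(c(0L, 1L, 2L, 2L), 2, 2, byrow = TRUE))
  mask <- build_three_intensity_mask(lab, bulk_intensities(14, 64, 149))
  expect_equal(mask$data[1, , ], matrix(c(14, 64, 149, 149), 2, 2,
                                        byrow = TRUE))
  expect_lte(length(unique(as.vector(mask$data))), 3L)

  ## all-soft map is constant at bulk[soft]
  lab1 <- tissue_label_map(array(1L, c(1, 4, 4)))
  expect_true(all(build_three_intensity_mask(lab1)$data == 65))

  ## phantom ground-truth labels + true levels reproduce the clean MRI
  ph <- small_phantom(shape = c(2, 64, 64), noise_sd = 0,
                      bias = list(type = "none"))
  lvl <- ph$config$tissue_mri_levels
  m <- build_three_intensity_mask(ph$labels,
                                  bulk_intensities(lvl[1], lvl[2], lvl[3]))
  expect_equal(m$data, ph$clean_mri$data)
})

test_that("ratio image is exact voxelwise division", {
  ph <- small_phantom(shape = c(2, 64, 64), noise_sd = 0)
  mask <- ph$clean_mri
  mri <- ph$clean_mri
  expect_true(all(compute_ratio_image(mri, mask)$data == 1))
  mri2 <- mri; mri2$data <- 2 * mri$data
  expect_true(all(compute_ratio_image(mri2, mask)$data == 2))
  ## mri = mask * b  =>  ratio == b exactly
  biased <- mri; biased$data <- mri$data * ph$bias_field$data
  expect_equal(compute_ratio_image(biased, mask)$data, ph$bias_field$data,
               tolerance = 1e-12)
  bad <- mask; bad$data[1] <- 0
  expect_error(compute_ratio_image(mri, bad), "positive")
})

test_that("box smoothing obeys the stated window conventions", {
  ## averaging preserves constants
  c5 <- volume(array(5, c(2, 30, 30)))
  expect_equal(smooth_ratio(c5, 10)$map$data, c5$data, tolerance = 1e-12)

  ## width 1 is the identity
  set.seed(1)
  r <- volume(array(runif(900), c(1, 30, 30)))
  expect_equal(smooth_ratio(r, 1)$map$data, r$data)

  ## single-pixel impulse +h spreads exactly h/100 over the 10x10 window
  h <- 30
  img <- matrix(10, 40, 40)
  img[20, 20] <- 10 + h
  sm <- smooth_ratio(volume(img), 10)$map$data[1, , ]
  bump <- sm - 10
  hit <- which(abs(bump - h / 100) < 1e-9, arr.ind = TRUE)
  expect_equal(nrow(hit), 100L)
  ## window [i - w/2, i + w/2 - 1]: pixel (r, c) sees the impulse at 20
  ## when 20 - w/2 <= r - ... equivalently rows 16..25
  expect_equal(sort(unique(hit[, 1])), 16:25)
  expect_equal(sort(unique(hit[, 2])), 16:25)
  expect_true(all(abs(bump[abs(bump - h / 100) > 1e-9]) < 1e-12))

  expect_error(smooth_ratio(volume(matrix(1, 5, 5)), 10), "exceeds")
})

test_that("intensity correction divides by the shading map", {
  ph <- small_phantom(shape = c(1, 48, 48), noise_sd = 0)
  mri <- ph$mri
  ones <- smooth_ratio(volume(array(1, dim(mri$data)),
                              spacing = mri$spacing), 1)
  expect_equal(correct_intensity(mri, ones)$data, mri$data)
  two <- ones; two$map$data <- two$map$data * 2
  expect_equal(correct_intensity(mri, two)$data, mri$data / 2)
  expect_error(correct_intensity(mri, smooth_ratio(volume(matrix(1, 8, 8)),
                                                   1)),
               "grid")
})

test_that("normalization recovers a noiseless bias-free phantom exactly", {
  ph <- small_phantom(shape = c(2, 96, 96), noise_sd = 0,
                      bias = list(type = "none"))
  lvl <- ph$config$tissue_mri_levels
  res <- normalize_mri(ph$mri, bulk_intensities(lvl[1], lvl[2], lvl[3]))
  ## ratio is piecewise constant 1 where segmentation is exact, so the
  ## shading map is 1 away from class boundaries and correction is exact
  boundary_free <- interior_mask(ph$labels, margin = 10L)
  expect_gt(mean(boundary_free), 0.1)
  expect_equal(res$corrected$data[boundary_free],
               ph$clean_mri$data[boundary_free], tolerance = 1e-9)
})

test_that("shading map recovery: smooth bias is estimated to < 2% interior RMSE", {
  ph <- small_phantom(shape = c(2, 128, 128), noise_sd = 0,
                      bias = list(type = "gaussian_blobs", amplitude = 0.3,
                                  scale = 40))
  lvl <- ph$config$tissue_mri_levels
  res <- normalize_mri(ph$mri, bulk_intensities(lvl[1], lvl[2], lvl[3]),
                       labels = ph$labels)
  interior <- interior_mask(ph$labels, margin = 10L)
  rel <- (res$shading$map$data[interior] - ph$bias_field$data[interior]) /
    ph$bias_field$data[interior]
  expect_lt(sqrt(mean(rel^2)), 0.02)
})

test_that("edges survive correction (step contrast ratio in [0.9, 1.1])", {
  ph <- small_phantom(shape = c(1, 128, 128), noise_sd = 0,
                      bias = list(type = "gaussian_blobs", amplitude = 0.3,
                                  scale = 40))
  lvl <- ph$config$tissue_mri_levels
  res <- normalize_mri(ph$mri, bulk_intensities(lvl[1], lvl[2], lvl[3]),
                       labels = ph$labels)
  ## fat/soft step contrast along the mid row, against the bias-free truth
  lab <- ph$labels$labels[1, , ]
  mid <- nrow(lab) %/% 2
  cols_fat <- which(lab[mid, ] == 2L)
  cols_soft <- which(lab[mid, ] == 1L)
  truth_step <- ph$clean_mri$data[1, mid, cols_fat[1]] -
    ph$clean_mri$data[1, mid, cols_soft[1]]
  corr_step <- res$corrected$data[1, mid, cols_fat[1]] -
    res$corrected$data[1, mid, cols_soft[1]]
  ## bulk equals the true levels here, so corrected and truth share a scale
  ratio <- corr_step / truth_step
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("corrected per-tissue means land at the bulk levels within 5%", {
  ph <- small_phantom(shape = c(2, 128, 128), noise_sd = 5,
                      bias = list(type = "gaussian_blobs", amplitude = 0.3,
                                  scale = 40))
  res <- normalize_mri(ph$mri, bulk_intensities(26, 125, 297))
  st <- tissue_stats(res$corrected, ph$labels)
  bulk <- c(26, 125, 297)
  for (code in 0:2) {
    m <- st$mean[st$tissue == code]
    expect_lt(abs(m - bulk[code + 1]) / bulk[code + 1], 0.05)
  }
})

test_that("correction reduces per-tissue CV for fat and soft tissue", {
  ph <- small_phantom(shape = c(2, 128, 128), noise_sd = 5,
                      bias = list(type = "gaussian_blobs", amplitude = 0.3,
                                  scale = 40))
  res <- normalize_mri(ph$mri, bulk_intensities(26, 125, 297),
                       labels = ph$labels)
  before <- tissue_stats(ph$mri, ph$labels)
  after <- tissue_stats(res$corrected, ph$labels)
  for (code in 1:2) {
    expect_lt(after$cv_percent[after$tissue == code],
              before$cv_percent[before$tissue == code])
  }
})

test_that("uniformly rescaled intensities normalize to identical volumes", {
  ## MRI gain differences between scanners cancel exactly: FCM is
  ## scale-equivariant and the ratio/shading/division chain is homogeneous
  ph <- small_phantom(shape = c(2, 96, 96), noise_sd = 0)
  res1 <- normalize_mri(ph$mri, bulk_intensities())
  scaled <- ph$mri; scaled$data <- 3.5 * ph$mri$data
  res2 <- normalize_mri(scaled, bulk_intensities())
  expect_equal(res2$corrected$data, res1$corrected$data, tolerance = 1e-6)
  st1 <- tissue_stats(res1$corrected, ph$labels)
  st2 <- tissue_stats(res2$corrected, ph$labels)
  expect_equal(st2$mean, st1$mean, tolerance = 0.05)
})
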