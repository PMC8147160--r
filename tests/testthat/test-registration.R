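test_that("mutual information behaves like an information measure", {
  ph <- small_phantom(shape = c(1, 96, 96), noise_sd = 5, seed = 3)
  a <- ph$mri
  ## spatial permutation destroys the joint structure
  set.seed(4)
  perm <- a
  perm$data[1, , ] <- matrix(sample(as.vector(a$data)), 96, 96)
  cfg <- mattes_config(samples = 4000, seed = 1)
  expect_gt(mattes_mi(a, a, cfg = cfg), mattes_mi(a, perm, cfg = cfg))

  ## independent noise: MI collapses to the small-sample bias floor
  set.seed(5)
  u1 <- volume(array(runif(50000), c(1, 200, 250)))
  u2 <- volume(array(runif(50000), c(1, 200, 250)))
  mi0 <- mattes_mi(u1, u2, cfg = mattes_config(bins = 50, samples = 5000,
                                               seed = 1))
  expect_lt(mi0, 0.15)
  expect_gt(mattes_mi(u1, u1, cfg = mattes_config(bins = 50,
                                                  samples = 5000,
                                                  seed = 1)),
            10 * mi0)
})

test_that("Gaussian image pair reproduces the closed-form MI", {
  set.seed(42)
  n <- 50000; rho <- 0.9
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  fx <- volume(array(x, c(1, 200, 250)))
  mv <- volume(array(y, c(1, 200, 250)))
  mi <- mattes_mi(fx, mv, cfg = mattes_config(bins = 50, samples = 50000,
                                              seed = 1))
  target <- -0.5 * log(1 - rho^2)   # 0.830 nats
  expect_lt(abs(mi - target) / target, 0.25)
})

test_that("MI is invariant to monotone affine intensity rescaling", {
  ph <- small_phantom(shape = c(1, 96, 96), noise_sd = 5, seed = 6)
  a <- ph$mri
  b <- ph$ct
  cfg <- mattes_config(samples = 4000, seed = 2)
  mi_ab <- mattes_mi(a, b, cfg = cfg)
  b2 <- b; b2$data <- 3 * b$data + 500
  a2 <- a; a2$data <- 0.25 * a$data - 40
  expect_equal(mattes_mi(a, b2, cfg = cfg), mi_ab, tolerance = 0.02)
  expect_equal(mattes_mi(a2, b, cfg = cfg), mi_ab, tolerance = 0.02)
})

test_that("the MI landscape peaks at the true alignment", {
  ph <- small_phantom(shape = c(1, 96, 96), noise_sd = 5, seed = 7)
  cfg <- mattes_config(samples = 4000, seed = 3)
  mi0 <- mattes_mi(ph$mri, ph$ct, cfg = cfg)
  for (axis in 2:3) for (sign in c(-1, 1)) {
    off <- c(0, 0, 0)
    off[axis] <- sign * 2 * ph$mri$spacing[axis]  # +/- 2 px
    expect_gt(mi0, mattes_mi(ph$mri, ph$ct, rigid_transform(translation =
                                                              off),
                             cfg = cfg))
  }
})

test_that("rigid registration recovers known transforms", {
  ph <- small_phantom(shape = c(1, 96, 96), noise_sd = 5, seed = 3)
  fixed <- ph$mri
  px <- fixed$spacing
  cfg <- mattes_config(samples = 3000, seed = 2)

  ## identity
  t_id <- rigid_register(fixed, fixed, cfg, free = c("r1", "t2", "t3"))
  expect_lt(max(abs(t_id$translation / px)), 0.1)
  expect_lt(abs(t_id$rotation[1]), 0.1)

  ## (3, -2) px in-plane translation, recovered within 0.5 px
  applied <- rigid_transform(translation = c(0, 3 * px[2], -2 * px[3]))
  moving <- resample(fixed, applied, fixed, fill = 0)
  t_tr <- rigid_register(fixed, moving, cfg, free = c("t2", "t3"))
  ## pull-back convention: the recovered transform is the inverse map
  expect_lt(abs(t_tr$translation[2] / px[2] + 3), 0.5)
  expect_lt(abs(t_tr$translation[3] / px[3] - 2), 0.5)

  ## 5 degree in-plane rotation, recovered within 1 degree
  rot <- resample(fixed, rigid_transform(rotation = c(5, 0, 0)), fixed,
                  fill = 0)
  t_rot <- rigid_register(fixed, rot, cfg, free = c("r1", "t2", "t3"))
  expect_lt(abs(t_rot$rotation[1] + 5), 1)
})

test_that("resampling is exact for identity, integer shifts and ramps", {
  ph <- small_phantom(shape = c(2, 48, 48), noise_sd = 3, seed = 9)
  v <- ph$mri
  ## identity on the same grid
  expect_equal(resample(v, rigid_transform(), v)$data, v$data,
               tolerance = 1e-12)
  ## integer-voxel translation = exact index shift with fill at the border
  shift <- resample(v, rigid_transform(translation = c(0, 2 * v$spacing[2],
                                                       0)), v, fill = -1)
  expect_equal(shift$data[, 1:46, ], v$data[, 3:48, ])
  expect_true(all(shift$data[, 47:48, ] == -1))
  ## half-voxel shift of a linear ramp: exact linear interpolation
  ramp <- volume(array(matrix(seq_len(48), 48, 48, byrow = TRUE),
                       c(1, 48, 48)))
  half <- resample(ramp, rigid_transform(translation = c(0, 0, 0.5)), ramp)
  expect_equal(half$data[1, , 2:47], ramp$data[1, , 2:47] + 0.5,
               tolerance = 1e-9)
  ## constants are preserved exactly
  cst <- volume(array(3, c(2, 20, 20)))
  rs <- resample(cst, rigid_transform(rotation = c(7, 0, 0)), cst,
                 fill = 3)
  expect_equal(rs$data, cst$data, tolerance = 1e-12)
})

test_that("deformation fields are applied, consistently with resampling", {
  ph <- small_phantom(shape = c(1, 48, 48), noise_sd = 3, seed = 10)
  v <- ph$mri
  d <- dim(v$data)
  zero <- array(0, c(d, 3))
  expect_equal(apply_deformation(v, zero, v)$data, v$data,
               tolerance = 1e-12)
  ## constant one-voxel field matches the equivalent rigid translation
  const <- zero; const[, , , 3] <- v$spacing[3]
  expect_equal(apply_deformation(v, const, v, fill = 0)$data,
               resample(v, rigid_transform(translation =
                                             c(0, 0, v$spacing[3])), v,
                        fill = 0)$data,
               tolerance = 1e-12)
  ## sinusoidal field applied, then its negation (approximate inverse):
  ## on a unit-slope ramp the intensity residual reads out the residual
  ## displacement in voxels, which stays below 0.2
  ramp <- volume(array(matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE),
                       c(1, d[2], d[3])), spacing = v$spacing)
  smooth_field <- zero
  colpos <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
  smooth_field[1, , , 3] <- 0.8 * sin(2 * pi * colpos / 48) * v$spacing[3]
  warped <- apply_deformation(ramp, smooth_field, ramp, fill = 0)
  back <- apply_deformation(warped, -smooth_field, ramp, fill = 0)
  resid <- abs(back$data - ramp$data)[1, 5:44, 5:44]
  expect_lt(max(resid), 0.2)
  expect_error(apply_deformation(v, zero[, , , 1:2, drop = FALSE], v),
               "shape")
})

test_that("transforms serialize to JSON and back", {
  dir <- withr::local_tempdir()
  t1 <- rigid_transform(c(1.5, 0, -2), c(3.25, -1, 0.5))
  p <- file.path(dir, "t.json")
  write_transform(t1, p)
  t2 <- read_transform(p)
  expect_equal(t2$rotation, t1$rotation)
  expect_equal(t2$translation, t1$translation)
  expect_null(t2$center)
})

test_that("metric preconditions are enforced", {
  a <- volume(array(runif(400), c(1, 20, 20)))
  cst <- volume(array(1, c(1, 20, 20)))
  expect_error(mattes_mi(a, cst, cfg = mattes_config(samples = 300)),
               "constant")
  far <- rigid_transform(translation = c(0, 1e5, 1e5))
  expect_error(mattes_mi(a, a, far, mattes_config(samples = 300)),
               "overlap")
  expect_error(mattes_config(bins = 1), "bins")
  expect_error(mattes_config(bins = 50, samples = 10), "samples")
})
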