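## Digital torso phantom: paired MRI/CT volumes with known tissue labels,
## a known smooth multiplicative bias field, and seeded noise.  Two presets
## emulate the acquisition conditions the package targets: a low-field
## (0.35 T) chest scan on an MR-LINAC and a 1.5 T diagnostic abdominal scan,
## whose per-tissue MRI levels differ by roughly a factor of two -- the
## inter-scanner intensity-range mismatch the normalization method exists to
## remove.

PHANTOM_PRESETS <- list(
  chest = list(
    spacing = c(3, 1.5, 1.5),
    ## per-tissue MRI levels (a.u.) and CT levels (HU): air/lung, soft, fat
    tissue_mri_levels = c(air_lung = 26, soft_tissue = 125, fat = 297),
    tissue_hu_levels = c(air_lung = -800, soft_tissue = 35, fat = -108)
  ),
  abdomen = list(
    spacing = c(8, 1.32, 1.32),
    tissue_mri_levels = c(air_lung = 65, soft_tissue = 298, fat = 533),
    tissue_hu_levels = c(air_lung = -822, soft_tissue = 32, fat = -86)
  )
)

#' Configuration for the digital torso phantom
#'
#' Axial slices contain an elliptical body with a subcutaneous fat ring
#' (outer 10% of the body radius), a soft-tissue interior, and air cavities:
#' two lungs for the chest preset, a small bowel-gas pocket for the abdomen
#' preset.  The exterior is air.  The clean MRI is a per-tissue level lookup;
#' a smooth multiplicative bias field and additive noise are applied on top,
#' and the paired ground-truth CT is a per-tissue HU lookup.
#'
#' @param preset `"chest"` (0.35 T MR-LINAC levels: air/lung 26, soft 125,
#'   fat 297 a.u.) or `"abdomen"` (1.5 T levels: air 65, soft 298, fat 533
#'   a.u.).  Presets differ only in geometry details, spacing and level
#'   tables; the processing code path is identical.
#' @param shape grid dimensions `(slices, rows, cols)`.
#' @param spacing voxel spacing mm; default from the preset.
#' @param tissue_mri_levels,tissue_hu_levels named numeric length-3 vectors
#'   (`air_lung`, `soft_tissue`, `fat`) overriding the preset tables.
#' @param bias bias-field spec: `list(type, amplitude, scale, n_blobs)` with
#'   `type` one of `"gaussian_blobs"`, `"linear_ramp"`, `"none"`; `amplitude`
#'   in `[0, 1)` (the field spans about `1 +/- amplitude` before mean
#'   renormalization); `scale` the blob standard deviation in in-plane
#'   pixels.
#' @param noise_sd additive MRI noise SD in a.u.
#' @param noise_kind `"gaussian"` or `"rician"`.
#' @param ct_noise_sd additive CT noise SD in HU (default 0).
#' @param seed integer seed controlling bias-blob placement and noise.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(preset = c("chest", "abdomen"),
                           shape = c(24, 256, 256),
                           spacing = NULL,
                           tissue_mri_levels = NULL,
                           tissue_hu_levels = NULL,
                           bias = list(type = "gaussian_blobs",
                                       amplitude = 0.3, scale = 40),
                           noise_sd = 5,
                           noise_kind = c("gaussian", "rician"),
                           ct_noise_sd = 0,
                           seed = 0L) {
  preset <- match.arg(preset)
  p <- PHANTOM_PRESETS[[preset]]
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be 3 positive integers", call. = FALSE)
  if (is.null(spacing)) spacing <- p$spacing
  if (is.null(tissue_mri_levels)) tissue_mri_levels <- p$tissue_mri_levels
  if (is.null(tissue_hu_levels)) tissue_hu_levels <- p$tissue_hu_levels
  bias <- utils::modifyList(list(type = "gaussian_blobs", amplitude = 0.3,
                                 scale = 40, n_blobs = 4L), as.list(bias))
  bias$type <- match.arg(bias$type, c("gaussian_blobs", "linear_ramp", "none"))
  if (bias$amplitude < 0 || bias$amplitude >= 1)
    stop("bias amplitude must lie in [0, 1)", call. = FALSE)
  if (noise_sd < 0 || ct_noise_sd < 0)
    stop("noise SDs must be non-negative", call. = FALSE)
  structure(list(
    preset = preset, shape = shape, spacing = as.numeric(spacing),
    tissue_mri_levels = tissue_mri_levels,
    tissue_hu_levels = tissue_hu_levels,
    bias = bias, noise_sd = noise_sd,
    noise_kind = match.arg(noise_kind), ct_noise_sd = ct_noise_sd,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

## Ground-truth label geometry.  Ellipses are defined as fractions of the
## grid; slice-to-slice radii are modulated by +/-5% with fixed phases so
## per-slice statistics vary without any RNG.
torso_geometry_labels <- function(shape, preset) {
  ns <- shape[1]; nr <- shape[2]; nc <- shape[3]
  if (nr < 16 || nc < 16)
    stop("grid too small for torso geometry (need >= 16 in-plane)",
         call. = FALSE)
  labels <- array(0L, dim = shape)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  a_row <- 0.34 * nr   # body semi-axis, row direction
  a_col <- 0.42 * nc   # body semi-axis, col direction
  if (a_row < 4 || a_col < 4)
    stop("degenerate geometry: body ellipse smaller than a few voxels",
         call. = FALSE)
  ring_frac <- 0.10    # fat ring = outer 10% of body radius
  row_idx <- matrix(seq_len(nr), nr, nc)
  col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (s in seq_len(ns)) {
    ph <- if (ns > 1) 2 * pi * (s - 1) / ns else 0
    mod_r <- 1 + 0.05 * sin(ph)
    mod_c <- 1 + 0.05 * cos(ph + 1)
    br <- a_row * mod_r; bc <- a_col * mod_c
    rnorm2 <- sqrt(((row_idx - cr) / br)^2 + ((col_idx - cc) / bc)^2)
    sl <- matrix(0L, nr, nc)
    sl[rnorm2 <= 1] <- 2L                       # fat ring (outermost body)
    sl[rnorm2 <= 1 - ring_frac] <- 1L           # soft-tissue interior
    if (preset == "chest") {
      for (side in c(-1, 1)) {
        lc_r <- cr - 0.05 * br
        lc_c <- cc + side * 0.45 * bc
        lr <- 0.45 * br * (1 - ring_frac)
        lc <- 0.30 * bc * (1 - ring_frac)
        inside <- (((row_idx - lc_r) / lr)^2 + ((col_idx - lc_c) / lc)^2) <= 1
        sl[inside & sl == 1L] <- 0L             # lungs
      }
    } else {
      gc_r <- cr + 0.30 * br
      gc_c <- cc - 0.15 * bc
      inside <- (((row_idx - gc_r) / (0.12 * br))^2 +
                 ((col_idx - gc_c) / (0.14 * bc))^2) <= 1
      sl[inside & sl == 1L] <- 0L               # bowel gas
    }
    labels[s, , ] <- sl
  }
  labels
}

#' Generate a smooth multiplicative bias field
#'
#' Produces a strictly positive smooth field with spatial mean 1 (within
#' 1e-3 after renormalization).  `gaussian_blobs` superposes seeded Gaussian
#' bumps, rescaled so the field spans about `1 +/- amplitude`;
#' `linear_ramp` spans exactly `[1 - amplitude, 1 + amplitude]` along the
#' column axis.  The field is constant along the slice axis (in-plane coil
#' shading is the regime the smoothing-based estimator targets).
#'
#' @param shape grid dims `(slices, rows, cols)`.
#' @param spec list with `type` (`"gaussian_blobs"`, `"linear_ramp"`,
#'   `"none"`), `amplitude` in `[0, 1)`, `scale` (blob SD, in-plane pixels),
#'   `n_blobs`.
#' @param seed integer seed for blob placement.
#' @return A `MAP`-modality [volume()].
#' @export
make_bias_field <- function(shape, spec, seed = 0L) {
  shape <- as.integer(shape)
  spec <- utils::modifyList(list(type = "gaussian_blobs", amplitude = 0.3,
                                 scale = 40, n_blobs = 4L), as.list(spec))
  if (spec$amplitude < 0 || spec$amplitude >= 1)
    stop("bias amplitude must lie in [0, 1)", call. = FALSE)
  nr <- shape[2]; nc <- shape[3]
  plane <- matrix(1, nr, nc)
  if (spec$type != "none" && spec$amplitude > 0) {
    if (spec$type == "linear_ramp") {
      ramp <- seq(-1, 1, length.out = nc)
      plane <- 1 + spec$amplitude * matrix(ramp, nr, nc, byrow = TRUE)
    } else {
      row_idx <- matrix(seq_len(nr), nr, nc)
      col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      bumps <- matrix(0, nr, nc)
      with_seed(seed, {
        for (b in seq_len(spec$n_blobs)) {
          ctr_r <- stats::runif(1, 0.2 * nr, 0.8 * nr)
          ctr_c <- stats::runif(1, 0.2 * nc, 0.8 * nc)
          amp <- stats::runif(1, -1, 1)
          s2 <- (spec$scale * stats::runif(1, 0.7, 1.3))^2
          bumps <- bumps + amp *
            exp(-((row_idx - ctr_r)^2 + (col_idx - ctr_c)^2) / (2 * s2))
        }
      })
      peak <- max(abs(bumps))
      if (peak > 0) plane <- 1 + spec$amplitude * bumps / peak
    }
  }
  field <- aperm(array(plane, dim = c(nr, nc, shape[1])), c(3, 1, 2))
  field <- field / mean(field)
  volume(field, modality = "MAP", units = "ratio")
}

#' Add seeded noise to a volume
#'
#' @param vol a [volume()].
#' @param sd noise standard deviation (same units as the volume).
#' @param kind `"gaussian"` (additive) or `"rician"` (magnitude of the
#'   signal plus two independent Gaussian channels of the given sd, the MR
#'   magnitude-image noise model).
#' @param seed integer seed.
#' @return A [volume()] with the same grid and metadata.
#' @export
add_noise <- function(vol, sd, kind = c("gaussian", "rician"), seed = 0L) {
  stopifnot_volume(vol)
  kind <- match.arg(kind)
  if (sd < 0) stop("'sd' must be non-negative", call. = FALSE)
  if (sd == 0) return(vol)
  n <- length(vol$data)
  data <- with_seed(seed, {
    if (kind == "gaussian") {
      vol$data + array(stats::rnorm(n, sd = sd), dim = dim(vol$data))
    } else {
      re <- vol$data + array(stats::rnorm(n, sd = sd), dim = dim(vol$data))
      im <- array(stats::rnorm(n, sd = sd), dim = dim(vol$data))
      sqrt(re^2 + im^2)
    }
  })
  out <- vol
  out$data <- data
  out
}

#' Generate a paired MRI/CT torso phantom with ground truth
#'
#' @param cfg a [phantom_config()].
#' @return A list of class `phantom_truth` with elements `mri` (bias and
#'   noise applied), `clean_mri` (pure per-tissue levels), `ct` (HU),
#'   `labels` ([tissue_label_map()]), `bias_field` (MAP volume) and
#'   `config`.  `mri` equals `clean_mri * bias_field` plus the seeded noise
#'   realization.
#' @export
make_torso_phantom <- function(cfg) {
  if (!inherits(cfg, "phantom_config"))
    stop("'cfg' must be a phantom_config", call. = FALSE)
  lab <- torso_geometry_labels(cfg$shape, cfg$preset)
  labels <- tissue_label_map(lab, spacing = cfg$spacing)
  lut_mri <- unname(cfg$tissue_mri_levels)
  lut_hu <- unname(cfg$tissue_hu_levels)
  clean <- array(lut_mri[as.vector(lab) + 1L], dim = cfg$shape)
  clean_mri <- volume(clean, spacing = cfg$spacing, modality = "MRI")
  bias <- make_bias_field(cfg$shape, cfg$bias, seed = cfg$seed)
  biased <- clean_mri
  biased$data <- clean_mri$data * bias$data
  mri <- add_noise(biased, cfg$noise_sd, cfg$noise_kind,
                   seed = cfg$seed + 1L)
  ct <- volume(array(lut_hu[as.vector(lab) + 1L], dim = cfg$shape),
               spacing = cfg$spacing, modality = "CT")
  if (cfg$ct_noise_sd > 0)
    ct <- add_noise(ct, cfg$ct_noise_sd, "gaussian", seed = cfg$seed + 2L)
  structure(list(mri = mri, clean_mri = clean_mri, ct = ct,
                 labels = labels, bias_field = bias, config = cfg),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> preset '%s', %s voxels, bias %s (amp %.2f), noise sd %g\n",
              x$config$preset, paste(x$config$shape, collapse = "x"),
              x$config$bias$type, x$config$bias$amplitude,
              x$config$noise_sd))
  invisible(x)
}
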