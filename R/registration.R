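#' Mattes mutual-information metric configuration
#'
#' @param bins number of uniformly spaced histogram bins (default 50).
#' @param samples number of voxel samples per metric evaluation (default
#'   500; increase for low-variance estimates).
#' @param seed RNG seed for sample drawing.  Each metric evaluation draws
#'   its samples afresh from this seed, so the metric is a deterministic,
#'   spatially smooth function of the transform.
#' @return A list of class `mattes_config` (fixed-image kernel order 0,
#'   moving-image kernel order 3).
#' @export
mattes_config <- function(bins = 50L, samples = 500L, seed = 0L) {
  bins <- as.integer(bins); samples <- as.integer(samples)
  if (bins < 2L) stop("'bins' must be >= 2", call. = FALSE)
  if (samples < bins) stop("'samples' must be >= bins", call. = FALSE)
  structure(list(bins = bins, samples = samples,
                 fixed_kernel_order = 0L, moving_kernel_order = 3L,
                 seed = as.integer(seed)),
            class = "mattes_config")
}

#' Rigid transform (rotation + translation)
#'
#' Maps fixed-image physical points to moving-image physical points:
#' `p' = R (p - center) + center + translation`, with `R` the composition of
#' rotations about the three grid axes (slice, row, col), applied in that
#' order.  Angle 1 is the in-plane rotation (about the slice axis).
#'
#' @param rotation numeric length-3, degrees about axes (slice, row, col).
#' @param translation numeric length-3, millimetres along (slice, row, col).
#' @param center rotation center in mm; `NULL` means the fixed-volume
#'   center, resolved when the transform is applied.
#' @return A list of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0),
                            translation = c(0, 0, 0), center = NULL) {
  rotation <- as.numeric(rotation); translation <- as.numeric(translation)
  if (length(rotation) != 3L || length(translation) != 3L ||
      !all(is.finite(c(rotation, translation))))
    stop("rotation and translation must be finite length-3", call. = FALSE)
  if (!is.null(center) && (length(center) != 3L || !all(is.finite(center))))
    stop("'center' must be finite length-3 or NULL", call. = FALSE)
  structure(list(rotation = rotation, translation = translation,
                 center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg): %s  trans (mm): %s\n",
              paste(format(x$rotation, digits = 4), collapse = ", "),
              paste(format(x$translation, digits = 4), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  ## rotation about axis 1 acts on the (row, col) plane, etc.
  r1 <- matrix(c(1, 0, 0,
                 0, cos(a[1]), -sin(a[1]),
                 0, sin(a[1]), cos(a[1])), 3, 3, byrow = TRUE)
  r2 <- matrix(c(cos(a[2]), 0, sin(a[2]),
                 0, 1, 0,
                 -sin(a[2]), 0, cos(a[2])), 3, 3, byrow = TRUE)
  r3 <- matrix(c(cos(a[3]), -sin(a[3]), 0,
                 sin(a[3]), cos(a[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  r1 %*% r2 %*% r3
}

volume_center_mm <- function(vol) (dim(vol$data) - 1) / 2 * vol$spacing

## physical fixed-space points (n x 3 mm) -> moving-space points (n x 3 mm)
transform_points <- function(t, pts, default_center) {
  ctr <- if (is.null(t$center)) default_center else t$center
  r <- rotation_matrix(t$rotation)
  sweep(t(r %*% t(sweep(pts, 2, ctr))), 2, ctr + t$translation, `+`)
}

## Trilinear interpolation of vol at continuous 0-based voxel coordinates
## (n x 3).  Returns NA outside the grid.
trilinear_sample <- function(vol, coords) {
  d <- dim(vol$data)
  out <- rep(NA_real_, nrow(coords))
  inside <- coords[, 1] >= 0 & coords[, 1] <= d[1] - 1 &
    coords[, 2] >= 0 & coords[, 2] <= d[2] - 1 &
    coords[, 3] >= 0 & coords[, 3] <= d[3] - 1
  if (!any(inside)) return(out)
  p <- coords[inside, , drop = FALSE]
  p0 <- floor(p)
  f <- p - p0
  i0 <- pmin(p0, matrix(d - 2, nrow(p0), 3, byrow = TRUE))
  i0 <- pmax(i0, 0)
  f <- p - i0
  arr <- vol$data
  at <- function(ds, dr, dc)   # neighbor indices clamped for extent-1 axes
    arr[cbind(pmin(i0[, 1] + ds + 1, d[1]), pmin(i0[, 2] + dr + 1, d[2]),
              pmin(i0[, 3] + dc + 1, d[3]))]
  v <- at(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    at(1, 0, 0) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
    at(0, 1, 0) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
    at(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    at(1, 1, 0) * f[, 1] * f[, 2] * (1 - f[, 3]) +
    at(1, 0, 1) * f[, 1] * (1 - f[, 2]) * f[, 3] +
    at(0, 1, 1) * (1 - f[, 1]) * f[, 2] * f[, 3] +
    at(1, 1, 1) * f[, 1] * f[, 2] * f[, 3]
  out[inside] <- v
  out
}

## Cubic B-spline Parzen kernel, support (-2, 2)
bspline3 <- function(u) {
  au <- abs(u)
  ifelse(au < 1, (4 - 6 * au^2 + 3 * au^3) / 6,
         ifelse(au < 2, (2 - au)^3 / 6, 0))
}

accumulate_at <- function(idx, w, n) {
  r <- rowsum(w, idx)
  out <- numeric(n)
  out[as.integer(rownames(r))] <- r
  out
}

#' Mattes mutual information between two volumes under a transform
#'
#' Estimates `MI = H(fixed) + H(moving) - H(fixed, moving)` in nats from a
#' Parzen-windowed joint histogram over a seeded uniform voxel sample of the
#' fixed image: a zero-order (box) kernel distributes each sample on the
#' fixed-intensity axis and a third-order (cubic) B-spline kernel on the
#' moving-intensity axis.  Bin edges span the 1st-99th intensity percentiles
#' of each image over the overlap region, the standard outlier guard.
#'
#' @param fixed,moving [volume()]s.
#' @param t a [rigid_transform()] mapping fixed physical space into moving
#'   physical space (identity by default).
#' @param cfg a [mattes_config()].
#' @return MI in nats (non-negative up to estimation error).
#' @export
mattes_mi <- function(fixed, moving, t = rigid_transform(),
                      cfg = mattes_config()) {
  stopifnot_volume(fixed); stopifnot_volume(moving)
  d <- dim(fixed$data)
  n <- prod(d)
  idx <- with_seed(cfg$seed,
                   if (cfg$samples >= n) seq_len(n)
                   else sample.int(n, cfg$samples))
  sub <- arrayInd(idx, d) - 1L
  pts_mm <- sweep(sub, 2, fixed$spacing, `*`)
  mov_mm <- transform_points(t, pts_mm, volume_center_mm(fixed))
  mov_vox <- sweep(mov_mm, 2, moving$spacing, `/`)
  mval <- trilinear_sample(moving, mov_vox)
  keep <- !is.na(mval)
  if (sum(keep) < cfg$bins)
    stop("empty (or nearly empty) overlap between fixed and moving volumes",
         call. = FALSE)
  fval <- fixed$data[idx][keep]
  mval <- mval[keep]
  if (max(fval) == min(fval) || max(mval) == min(mval))
    stop("constant image intensities in the overlap region", call. = FALSE)
  nb <- cfg$bins
  frange <- stats::quantile(fval, c(0.01, 0.99), names = FALSE)
  mrange <- stats::quantile(mval, c(0.01, 0.99), names = FALSE)
  if (frange[2] <= frange[1]) frange <- range(fval)
  if (mrange[2] <= mrange[1]) mrange <- range(mval)
  fbw <- (frange[2] - frange[1]) / nb
  mbw <- (mrange[2] - mrange[1]) / nb
  ## zero-order kernel on the fixed axis: plain binning (clamped)
  fbin <- pmin(pmax(floor((fval - frange[1]) / fbw) + 1, 1), nb)
  ## cubic B-spline on the moving axis: each sample spreads over 4 bins
  z <- (mval - mrange[1]) / mbw - 0.5    # continuous bin coordinate, 0-based
  z0 <- floor(z)
  joint <- numeric(nb * nb)
  for (off in -1:2) {
    mbin <- pmin(pmax(z0 + off + 1, 1), nb)
    w <- bspline3(z - (z0 + off))
    joint <- joint + accumulate_at(fbin + (mbin - 1) * nb, w, nb * nb)
  }
  joint <- joint / sum(joint)
  pj <- matrix(joint, nb, nb)
  pf <- rowSums(pj)
  pm <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (pf[row(pj)[nz]] * pm[col(pj)[nz]])))
}

#' Rigid registration by mutual-information maximization
#'
#' Derivative-free multi-start coordinate search: at each of two resolution
#' levels (in-plane mean-pooled by 2, then full resolution), parameters are
#' optimized one at a time by golden-section line search over a shrinking
#' bracket, for a fixed number of sweeps.  Deterministic given the metric
#' seed.
#'
#' @param fixed,moving [volume()]s (the fixed image defines the sample
#'   grid).
#' @param cfg a [mattes_config()].
#' @param free character subset of `c("r1","r2","r3","t1","t2","t3")`
#'   naming the free parameters (rotations deg, translations mm); defaults
#'   to all six.  Thin volumes typically free only the in-plane parameters
#'   `c("r1", "t2", "t3")`.
#' @param starts list of [rigid_transform()]s used as multi-start initial
#'   guesses; default is the identity.
#' @param rot_step,trans_step initial bracket half-widths (degrees, mm).
#' @param sweeps coordinate-descent sweeps per resolution level.
#' @param levels number of resolution levels (2 or 1).
#' @return A [rigid_transform()] with attributes `mi` (achieved metric) and
#'   `converged` (logical: final sweep moved every parameter by less than
#'   1% of its initial step; the best transform found is always returned).
#' @export
rigid_register <- function(fixed, moving, cfg = mattes_config(samples = 2000L),
                           free = c("r1", "r2", "r3", "t1", "t2", "t3"),
                           starts = list(rigid_transform()),
                           rot_step = 10, trans_step = 10,
                           sweeps = 3L, levels = 2L) {
  stopifnot_volume(fixed); stopifnot_volume(moving)
  free <- match.arg(free, c("r1", "r2", "r3", "t1", "t2", "t3"),
                    several.ok = TRUE)
  par_of <- function(t) c(t$rotation, t$translation)
  to_transform <- function(p) rigid_transform(p[1:3], p[4:6])
  downsample2 <- function(vol) {
    d <- dim(vol$data)
    nr <- d[2] %/% 2L; nc <- d[3] %/% 2L
    arr <- array(0, c(d[1], nr, nc))
    a <- vol$data
    for (s in seq_len(d[1])) {
      m <- a[s, seq_len(2 * nr), seq_len(2 * nc)]
      arr[s, , ] <- (m[seq(1, 2 * nr, 2), seq(1, 2 * nc, 2)] +
                     m[seq(2, 2 * nr, 2), seq(1, 2 * nc, 2)] +
                     m[seq(1, 2 * nr, 2), seq(2, 2 * nc, 2)] +
                     m[seq(2, 2 * nr, 2), seq(2, 2 * nc, 2)]) / 4
    }
    volume(arr, spacing = vol$spacing * c(1, 2, 2), modality = vol$modality,
           units = vol$units)
  }
  free_idx <- match(free, c("r1", "r2", "r3", "t1", "t2", "t3"))
  steps0 <- c(rep(rot_step, 3), rep(trans_step, 3))
  best_p <- NULL; best_mi <- -Inf; best_conv <- FALSE
  pyramid <- list(list(fixed = fixed, moving = moving))
  if (levels >= 2L && all(dim(fixed$data)[2:3] >= 32L))
    pyramid <- c(list(list(fixed = downsample2(fixed),
                           moving = downsample2(moving))), pyramid)
  for (start in starts) {
    p <- par_of(start)
    conv <- FALSE
    for (lev in seq_along(pyramid)) {
      fx <- pyramid[[lev]]$fixed; mv <- pyramid[[lev]]$moving
      obj <- function(pp) mattes_mi(fx, mv, to_transform(pp), cfg)
      steps <- steps0 / lev            # tighter brackets at full resolution
      for (sw in seq_len(sweeps)) {
        moved <- 0
        for (j in free_idx) {
          f1 <- function(x) { pp <- p; pp[j] <- x; obj(pp) }
          o <- stats::optimize(f1, lower = p[j] - steps[j],
                               upper = p[j] + steps[j], maximum = TRUE,
                               tol = steps[j] * 1e-3)
          moved <- max(moved, abs(o$maximum - p[j]) / steps0[j])
          p[j] <- o$maximum
        }
        steps <- steps / 2
        if (moved < 0.01) break
      }
      conv <- moved < 0.01
    }
    mi <- mattes_mi(fixed, moving, to_transform(p), cfg)
    if (mi > best_mi) { best_mi <- mi; best_p <- p; best_conv <- conv }
  }
  if (!best_conv)
    warning("coordinate search did not converge; returning best transform ",
            "found", call. = FALSE)
  out <- to_transform(best_p)
  attr(out, "mi") <- best_mi
  attr(out, "converged") <- best_conv
  out
}

#' Resample a volume onto a reference grid under a rigid transform
#'
#' Pulls back moving-image intensities to the reference grid by trilinear
#' interpolation: each reference voxel center is mapped through the
#' transform into moving physical space and sampled there.  Voxels mapping
#' outside the moving field of view take `fill`.
#'
#' @param moving [volume()] to resample.
#' @param t a [rigid_transform()] (fixed/reference space to moving space).
#' @param reference [volume()] whose grid and spacing define the output.
#' @param fill out-of-field value; default -1000 for CT-like volumes, else 0.
#' @return A [volume()] on the reference grid with the moving volume's
#'   modality and units.
#' @export
resample <- function(moving, t, reference, fill = NULL) {
  stopifnot_volume(moving); stopifnot_volume(reference)
  if (is.null(fill))
    fill <- if (moving$modality %in% c("CT", "PSEUDO_CT")) -1000 else 0
  d <- dim(reference$data)
  sub <- arrayInd(seq_len(prod(d)), d) - 1L
  pts_mm <- sweep(sub, 2, reference$spacing, `*`)
  mov_mm <- transform_points(t, pts_mm, volume_center_mm(reference))
  mov_vox <- sweep(mov_mm, 2, moving$spacing, `/`)
  vals <- trilinear_sample(moving, mov_vox)
  vals[is.na(vals)] <- fill
  volume(array(vals, dim = d), spacing = reference$spacing,
         modality = moving$modality, units = moving$units)
}

#' Warp a volume by an externally supplied deformation field
#'
#' Applies (does not estimate) a dense displacement field by trilinear
#' pull-back: reference voxel at physical position `p` samples the moving
#' volume at `p + field(p)`.  This is the hook for deformable registration
#' computed by an external tool.
#'
#' @param moving [volume()] to warp.
#' @param field 4-D numeric array `(slice, row, col, 3)` of displacements in
#'   millimetres on the reference grid.
#' @param reference [volume()] defining the output grid.
#' @param fill out-of-field value, as in [resample()].
#' @return A warped [volume()] on the reference grid.
#' @export
apply_deformation <- function(moving, field, reference, fill = NULL) {
  stopifnot_volume(moving); stopifnot_volume(reference)
  d <- dim(reference$data)
  if (!identical(dim(field), c(d, 3L)) && !identical(dim(field), c(d, 3)))
    stop("'field' must have shape (slice, row, col, 3) on the reference ",
         "grid", call. = FALSE)
  if (is.null(fill))
    fill <- if (moving$modality %in% c("CT", "PSEUDO_CT")) -1000 else 0
  sub <- arrayInd(seq_len(prod(d)), d) - 1L
  pts_mm <- sweep(sub, 2, reference$spacing, `*`)
  disp <- matrix(field, ncol = 3L)
  mov_vox <- sweep(pts_mm + disp, 2, moving$spacing, `/`)
  vals <- trilinear_sample(moving, mov_vox)
  vals[is.na(vals)] <- fill
  volume(array(vals, dim = d), spacing = reference$spacing,
         modality = moving$modality, units = moving$units)
}

#' Serialize a rigid transform to JSON
#' @param t a [rigid_transform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(list(rotation_deg = t$rotation,
                            translation_mm = t$translation,
                            center_mm = t$center),
                       path, auto_unbox = FALSE, digits = NA, null = "null")
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path file written by [write_transform()].
#' @return A [rigid_transform()].
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$rotation_deg, x$translation_mm,
                  if (length(x$center_mm) == 3) x$center_mm else NULL)
}
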