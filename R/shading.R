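#' Bulk tissue intensity table
#'
#' One bulk MRI intensity level (a.u.) per tissue class, used to build the
#' three-intensity mask.  The defaults (air/lung 18, soft tissue 65, fat
#' 149 a.u.) put the normalized scale at the per-tissue levels a calibrated
#' low-field torso protocol produces after correction; they are a stand-in
#' for a site-specific cohort mean table and should be overridden with one
#' where available.
#'
#' @param air_lung,soft_tissue,fat strictly positive bulk levels (a.u.).
#' @return Named numeric vector of class `bulk_intensities`, indexed by
#'   tissue code 0, 1, 2.
#' @export
bulk_intensities <- function(air_lung = 18, soft_tissue = 65, fat = 149) {
  b <- c(air_lung = air_lung, soft_tissue = soft_tissue, fat = fat)
  if (anyNA(b) || !all(is.finite(b)) || any(b <= 0))
    stop("bulk intensities must be finite and strictly positive",
         call. = FALSE)
  structure(as.numeric(b), names = names(b), class = "bulk_intensities")
}

#' Replace each tissue class by its bulk intensity
#'
#' Voxelwise lookup `output(v) = bulk[labels(v)]`, producing the
#' three-intensity mask: an image holding at most three distinct values.
#'
#' @param labels a [tissue_label_map()].
#' @param bulk a [bulk_intensities()] table (or any positive length-3
#'   vector ordered air/lung, soft, fat).
#' @return A `MAP`-modality [volume()].
#' @export
build_three_intensity_mask <- function(labels, bulk = bulk_intensities()) {
  if (!inherits(labels, "tissue_label_map"))
    stop("'labels' must be a tissue_label_map", call. = FALSE)
  bulk <- as.numeric(bulk)
  if (length(bulk) != 3L || any(!is.finite(bulk)) || any(bulk <= 0))
    stop("'bulk' must be 3 positive finite levels", call. = FALSE)
  mask <- array(bulk[as.vector(labels$labels) + 1L], dim = dim(labels$labels))
  volume(mask, spacing = labels$spacing, modality = "MAP", units = "a.u.")
}

#' Ratio image between an MRI and its three-intensity mask
#'
#' Voxelwise `mri / mask`.  Where the segmentation and bulk table are exact,
#' the ratio image equals the multiplicative inhomogeneity field (plus
#' noise); its low-frequency content is what the shading map extracts.
#'
#' @param mri MRI [volume()].
#' @param mask strictly positive [volume()] on the same grid.
#' @return A `MAP`-modality [volume()].
#' @export
compute_ratio_image <- function(mri, mask) {
  stopifnot_volume(mri); stopifnot_volume(mask)
  check_same_grid(mri, mask, "mri and mask")
  if (any(mask$data <= 0))
    stop("mask must be strictly positive everywhere", call. = FALSE)
  volume(mri$data / mask$data, spacing = mri$spacing, modality = "MAP",
         units = "ratio")
}

## 2-D moving-average (box) filter on a matrix with edge replication.
## Even widths use the window [i - w/2, i + w/2 - 1] on each axis; odd
## widths are centered.  Implemented with padded cumulative sums, so cost is
## independent of the width.
box_smooth_matrix <- function(x, width) {
  w <- as.integer(width)
  nr <- nrow(x); nc <- ncol(x)
  if (w > nr || w > nc)
    stop("smoothing width exceeds slice extent", call. = FALSE)
  if (w == 1L) return(x)
  lo <- if (w %% 2L == 0L) w %/% 2L else (w - 1L) %/% 2L  # pixels before i
  hi <- w - 1L - lo                                        # pixels after i
  pad_axis <- function(m, lo, hi) {
    rbind(m[rep(1L, lo), , drop = FALSE], m,
          m[rep(nrow(m), hi), , drop = FALSE])
  }
  box_axis <- function(m, lo, hi, w) {
    p <- pad_axis(m, lo, hi)
    cs <- rbind(0, apply(p, 2L, cumsum))
    (cs[(w + 1L):(nrow(p) + 1L), , drop = FALSE] -
       cs[1L:(nrow(p) + 1L - w), , drop = FALSE]) / w
  }
  y <- box_axis(x, lo, hi, w)            # rows
  t(box_axis(t(y), lo, hi, w))           # cols
}

#' Smooth a ratio image into a shading map
#'
#' Applies a square moving-average filter of the given width to every axial
#' slice independently (2-D, because in-plane pixels are several times finer
#' than the slice spacing).  Borders replicate edge values; the result is
#' clamped below at `1e-6 *` its median so the subsequent division is safe
#' in all-air regions.
#'
#' @param ratio ratio-image [volume()].
#' @param width filter width in pixels (default 10).  Even widths average
#'   over `[i - width/2, i + width/2 - 1]` on each in-plane axis.
#' @return A list of class `shading_map`: `map` (MAP volume, strictly
#'   positive) and `smoothing_width`.
#' @export
smooth_ratio <- function(ratio, width = 10L) {
  stopifnot_volume(ratio)
  width <- as.integer(width)
  if (width < 1L) stop("'width' must be >= 1", call. = FALSE)
  d <- dim(ratio$data)
  out <- array(0, dim = d)
  for (s in seq_len(d[1]))
    out[s, , ] <- box_smooth_matrix(ratio$data[s, , ], width)
  eps <- 1e-6 * stats::median(out)
  if (!is.finite(eps) || eps <= 0) eps <- .Machine$double.eps
  out <- pmax(out, eps)
  structure(list(
    map = volume(out, spacing = ratio$spacing, modality = "MAP",
                 units = "ratio"),
    smoothing_width = width
  ), class = "shading_map")
}

#' @export
print.shading_map <- function(x, ...) {
  cat(sprintf("<shading_map> width %d px, range [%.4g, %.4g]\n",
              x$smoothing_width, min(x$map$data), max(x$map$data)))
  invisible(x)
}

#' Divide an MRI by its shading map
#'
#' The shading map holds only the slowly varying intensity differences, so
#' division normalizes per-tissue levels while preserving high
#' spatial-frequency content (edges).
#'
#' @param mri MRI [volume()].
#' @param shading a `shading_map` from [smooth_ratio()] (or a positive MAP
#'   volume).
#' @return Corrected MRI [volume()], units `"a.u. (normalized)"`.
#' @export
correct_intensity <- function(mri, shading) {
  stopifnot_volume(mri)
  map <- if (inherits(shading, "shading_map")) shading$map else shading
  stopifnot_volume(map, "shading")
  check_same_grid(mri, map, "mri and shading map")
  if (any(map$data <= 0))
    stop("shading map must be strictly positive", call. = FALSE)
  volume(mri$data / map$data, spacing = mri$spacing, modality = "MRI",
         units = "a.u. (normalized)")
}

#' MRI intensity normalization via a shading map
#'
#' The full normalization chain: segment the MRI into air/lung, soft tissue
#' and fat with fuzzy c-means; replace each class by its bulk level to form
#' the three-intensity mask; divide the MRI by the mask to get a ratio
#' image; smooth the ratio with a `width`-pixel moving average into the
#' shading map; divide the MRI by the shading map.
#'
#' @param mri MRI [volume()].
#' @param bulk a [bulk_intensities()] table.
#' @param fcm_cfg an [fcm_config()].
#' @param width smoothing width in pixels (default 10).
#' @param labels optional precomputed [tissue_label_map()]; when supplied
#'   the segmentation stage is skipped.
#' @return A list of class `normalization_result`: `corrected` (volume),
#'   `shading` (shading_map), `labels` (tissue_label_map), `mask`, `ratio`.
#' @export
normalize_mri <- function(mri, bulk = bulk_intensities(),
                          fcm_cfg = fcm_config(), width = 10L,
                          labels = NULL) {
  stopifnot_volume(mri)
  if (is.null(labels)) labels <- segment_tissues(mri, fcm_cfg)
  mask <- build_three_intensity_mask(labels, bulk)
  ratio <- compute_ratio_image(mri, mask)
  shading <- smooth_ratio(ratio, width)
  corrected <- correct_intensity(mri, shading)
  structure(list(corrected = corrected, shading = shading, labels = labels,
                 mask = mask, ratio = ratio),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("<normalization_result>\n")
  print(x$corrected)
  print(x$shading)
  invisible(x)
}
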