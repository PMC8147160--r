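#' Extract pointwise MRI-CT intensity pairs from registered volumes
#'
#' For each requested slice and tissue class, voxels inside the class mask
#' are sorted by MRI intensity (ties broken by voxel scan order) and sampled
#' at evenly spaced rank positions `round(j * (M - 1) / (n - 1))`,
#' `j = 0..n-1`, so the selection always includes the minimum and maximum
#' MRI intensity and covers the range evenly by quantile.  Each selected
#' voxel contributes its (MRI intensity, CT HU) pair.  Default counts per
#' slice are 25 for lung and fat and 50 for soft tissue.
#'
#' @param mri corrected-MRI [volume()].
#' @param ct_registered CT [volume()] on the same grid (registered to the
#'   MRI).
#' @param labels [tissue_label_map()] on the same grid.
#' @param slices integer axial slice indices (1-based).
#' @param counts named vector of pairs per slice per tissue:
#'   `c(air_lung = 25, soft_tissue = 50, fat = 25)`.
#' @param role dataset role tag (`"training"`, `"validation"`, `"testing"`).
#' @return A data.frame of class `intensity_pair_set` with columns
#'   `mri_au`, `ct_hu`, `tissue` (code), `slice`, sorted by MRI intensity
#'   within each (slice, tissue) group; attribute `role`.  A class mask
#'   with fewer voxels than requested contributes all of them with a
#'   warning; an empty mask is skipped with a warning.
#' @export
extract_pairs <- function(mri, ct_registered, labels,
                          slices = c(2L, 4L, 6L, 8L),
                          counts = c(air_lung = 25L, soft_tissue = 50L,
                                     fat = 25L),
                          role = c("training", "validation", "testing")) {
  stopifnot_volume(mri); stopifnot_volume(ct_registered)
  role <- match.arg(role)
  check_same_grid(mri, ct_registered, "mri and registered ct")
  if (!identical(dim(mri$data), dim(labels$labels)))
    stop("mri and labels must share one grid", call. = FALSE)
  d <- dim(mri$data)
  slices <- as.integer(slices)
  if (any(slices < 1L | slices > d[1]))
    stop("slice indices out of range 1..", d[1], call. = FALSE)
  counts <- counts[c("air_lung", "soft_tissue", "fat")]
  if (anyNA(counts) || any(counts < 1L))
    stop("'counts' must name positive air_lung/soft_tissue/fat counts",
         call. = FALSE)
  rows <- list()
  for (s in slices) {
    mri_sl <- as.vector(mri$data[s, , ])
    ct_sl <- as.vector(ct_registered$data[s, , ])
    lab_sl <- as.vector(labels$labels[s, , ])
    for (code in 0:2) {
      n_req <- as.integer(counts[[code + 1L]])
      in_mask <- which(lab_sl == code)
      m <- length(in_mask)
      if (m == 0L) {
        warning(sprintf("slice %d: empty %s mask, skipped", s,
                        TISSUE_NAMES[[as.character(code)]]), call. = FALSE)
        next
      }
      ord <- in_mask[order(mri_sl[in_mask], in_mask)]
      if (m < n_req) {
        warning(sprintf(
          "slice %d: %s mask has %d < %d voxels; taking all", s,
          TISSUE_NAMES[[as.character(code)]], m, n_req), call. = FALSE)
        sel <- ord
      } else if (n_req == 1L) {
        sel <- ord[1L]
      } else {
        j <- 0:(n_req - 1L)
        sel <- ord[floor(j * (m - 1) / (n_req - 1)) + 1L]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        mri_au = mri_sl[sel], ct_hu = ct_sl[sel], tissue = code, slice = s)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mri_au = numeric(0), ct_hu = numeric(0),
               tissue = integer(0), slice = integer(0))
  rownames(out) <- NULL
  structure(out, role = role, class = c("intensity_pair_set", "data.frame"))
}

#' Split soft-tissue pairs into low- and high-intensity halves
#'
#' Per slice, the soft-tissue pairs are split at the median MRI intensity
#' rank: the lower half feeds the low-density soft-tissue template and the
#' upper half the high-density one.  Odd counts put the extra pair in the
#' low half.  The split is by rank, so tied intensities still split evenly.
#'
#' @param pairs an [extract_pairs()] result.
#' @return A list with `low` and `high` `intensity_pair_set`s (soft-tissue
#'   rows only).
#' @export
split_soft_tissue <- function(pairs) {
  soft <- pairs[pairs$tissue == 1L, , drop = FALSE]
  if (nrow(soft) == 0L) stop("no soft-tissue pairs present", call. = FALSE)
  low_rows <- integer(0); high_rows <- integer(0)
  for (s in unique(soft$slice)) {
    idx <- which(soft$slice == s)
    idx <- idx[order(soft$mri_au[idx], idx)]
    n_low <- ceiling(length(idx) / 2)
    low_rows <- c(low_rows, idx[seq_len(n_low)])
    high_rows <- c(high_rows, idx[-seq_len(n_low)])
  }
  keep_attrs <- function(df) {
    rownames(df) <- NULL
    structure(df, role = attr(pairs, "role"),
              class = c("intensity_pair_set", "data.frame"))
  }
  list(low = keep_attrs(soft[low_rows, , drop = FALSE]),
       high = keep_attrs(soft[high_rows, , drop = FALSE]))
}

TEMPLATE_KINDS <- c("lung", "soft_low", "soft_high", "fat")

#' Build a phantom-template image pair from intensity pairs
#'
#' Lays the pairs out on a square grid of constant blocks: block `b` holds
#' pair `b`'s MRI intensity in the MRI image and its CT HU in the CT image,
#' with pairs placed in ascending MRI order, row-major.  Surplus blocks (a
#' square grid rarely matches the pair count exactly) cycle through the
#' pairs again.  At every pixel the (MRI, CT) value pair is one of the input
#' pairs, which is the property the patch network trains on; the exact
#' layout is otherwise immaterial.
#'
#' @param pairs an `intensity_pair_set` (>= 1 row).
#' @param kind one of `"lung"`, `"soft_low"`, `"soft_high"`, `"fat"`.
#' @param block_px block edge length in pixels (default 40; must give a
#'   template at least as large as the 32-px patch in both dimensions).
#' @param grid optional `c(nrow_blocks, ncol_blocks)`; default the smallest
#'   square grid holding all pairs.
#' @return A list of class `phantom_template_pair`: `mri_image`,
#'   `ct_image` (matrices), `region_map` (block index per pixel),
#'   `template_kind`, `pairs`.
#' @export
build_template_pair <- function(pairs, kind = TEMPLATE_KINDS,
                                block_px = 40L, grid = NULL) {
  kind <- match.arg(kind)
  if (nrow(pairs) < 1L) stop("need at least one intensity pair",
                             call. = FALSE)
  block_px <- as.integer(block_px)
  ord <- order(pairs$mri_au)
  mri_vals <- pairs$mri_au[ord]
  ct_vals <- pairs$ct_hu[ord]
  n <- length(mri_vals)
  if (is.null(grid)) {
    side <- ceiling(sqrt(n))
    grid <- c(side, side)
  }
  grid <- as.integer(grid)
  if (prod(grid) < n)
    stop("template grid too small for the pair count", call. = FALSE)
  h <- grid[1] * block_px; w <- grid[2] * block_px
  if (h < 32L || w < 32L)
    stop("template smaller than the 32-px patch size; increase block_px",
         call. = FALSE)
  block_row <- (seq_len(h) - 1L) %/% block_px          # 0-based block coords
  block_col <- (seq_len(w) - 1L) %/% block_px
  region <- outer(block_row, block_col,
                  function(r, c) r * grid[2] + c) + 1L  # row-major block id
  pair_of_block <- ((seq_len(prod(grid)) - 1L) %% n) + 1L
  pair_idx <- matrix(pair_of_block[region], h, w)
  structure(list(
    mri_image = matrix(mri_vals[pair_idx], h, w),
    ct_image = matrix(ct_vals[pair_idx], h, w),
    region_map = region, template_kind = kind,
    pairs = data.frame(mri_au = mri_vals, ct_hu = ct_vals)
  ), class = "phantom_template_pair")
}

#' Build the four standard templates from an intensity pair set
#'
#' Lung and fat templates take their classes' pairs directly; the
#' soft-tissue pairs are split per slice into low/high halves via
#' [split_soft_tissue()].
#'
#' @param pairs an [extract_pairs()] result containing all three classes.
#' @param block_px block size forwarded to [build_template_pair()].
#' @return Named list of four `phantom_template_pair`s: `lung`,
#'   `soft_low`, `soft_high`, `fat`.
#' @export
build_templates <- function(pairs, block_px = 40L) {
  soft <- split_soft_tissue(pairs)
  list(
    lung = build_template_pair(pairs[pairs$tissue == 0L, ], "lung",
                               block_px),
    soft_low = build_template_pair(soft$low, "soft_low", block_px),
    soft_high = build_template_pair(soft$high, "soft_high", block_px),
    fat = build_template_pair(pairs[pairs$tissue == 2L, ], "fat", block_px)
  )
}

#' Randomly crop paired 32x32 / 18x18 patches from templates
#'
#' Draws `n_per_template` uniformly random 32x32 crops from each template's
#' MRI image; the label is the centered 18x18 crop of the CT image at the
#' same location (7-px margin on every side).  Deterministic for a fixed
#' seed.
#'
#' @param templates a `phantom_template_pair` or list of them.
#' @param n_per_template crops per template.
#' @param seed integer RNG seed.
#' @return A list of class `paired_patch_set`: `inputs` `(N, 32, 32)`
#'   array, `labels` `(N, 18, 18)` array, `template_kind` (length N),
#'   `seed`.
#' @export
crop_patches <- function(templates, n_per_template, seed = 0L) {
  if (inherits(templates, "phantom_template_pair"))
    templates <- list(templates)
  n_per_template <- as.integer(n_per_template)
  if (n_per_template < 1L) stop("'n_per_template' must be >= 1",
                                call. = FALSE)
  patch <- 32L; label <- 18L; margin <- (patch - label) %/% 2L
  total <- n_per_template * length(templates)
  inputs <- array(0, c(total, patch, patch))
  labels <- array(0, c(total, label, label))
  kinds <- character(total)
  k <- 0L
  with_seed(seed, {
    for (tp in templates) {
      h <- nrow(tp$mri_image); w <- ncol(tp$mri_image)
      if (h < patch || w < patch)
        stop("template smaller than the 32-px patch", call. = FALSE)
      r0 <- sample.int(h - patch + 1L, n_per_template, replace = TRUE)
      c0 <- sample.int(w - patch + 1L, n_per_template, replace = TRUE)
      for (i in seq_len(n_per_template)) {
        k <- k + 1L
        rr <- r0[i]:(r0[i] + patch - 1L)
        cc <- c0[i]:(c0[i] + patch - 1L)
        inputs[k, , ] <- tp$mri_image[rr, cc]
        labels[k, , ] <- tp$ct_image[rr[(margin + 1L):(margin + label)],
                                     cc[(margin + 1L):(margin + label)]]
        kinds[k] <- tp$template_kind
      }
    }
  })
  structure(list(inputs = inputs, labels = labels, template_kind = kinds,
                 seed = as.integer(seed)),
            class = "paired_patch_set")
}

#' @export
print.paired_patch_set <- function(x, ...) {
  cat(sprintf("<paired_patch_set> %d patches (32x32 -> 18x18), seed %d\n",
              dim(x$inputs)[1], x$seed))
  invisible(x)
}

#' Write intensity pairs to CSV
#' @param pairs an [extract_pairs()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  df <- as.data.frame(pairs)
  df$role <- attr(pairs, "role") %||% "training"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read intensity pairs from CSV
#' @param path file written by [write_pairs()].
#' @return An `intensity_pair_set`.
#' @export
read_pairs <- function(path) {
  df <- utils::read.csv(path)
  role <- if ("role" %in% names(df)) df$role[1] else "training"
  structure(df[, c("mri_au", "ct_hu", "tissue", "slice")], role = role,
            class = c("intensity_pair_set", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
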