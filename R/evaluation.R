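#' Coefficient of variation, percent
#'
#' `100 * sd / |mean|`.  The absolute mean makes CVs of negative-HU tissues
#' (fat, lung) positive, the convention used throughout the tissue reports.
#'
#' @param mean,sd per-tissue mean and standard deviation.
#' @return CV in percent (not rounded; reports round to 2 decimals).
#' @export
cv_percent <- function(mean, sd) 100 * sd / abs(mean)

#' Voxels far from tissue-class boundaries
#'
#' Marks voxels whose entire in-plane Chebyshev neighborhood of radius
#' `margin` shares their tissue label.  Shading-map accuracy is assessed on
#' this interior because the smoothing window necessarily mixes classes
#' within `margin` pixels of a boundary.
#'
#' @param labels a [tissue_label_map()].
#' @param margin neighborhood radius in pixels (default 10).
#' @return Logical array on the label grid.
#' @export
interior_mask <- function(labels, margin = 10L) {
  d <- dim(labels$labels)
  w <- 2L * as.integer(margin) + 1L
  out <- array(FALSE, d)
  for (s in seq_len(d[1])) {
    sl <- labels$labels[s, , ]
    ok <- matrix(TRUE, d[2], d[3])
    for (code in 0:2) {
      if (!any(sl == code)) next
      ind <- matrix(as.numeric(sl == code), d[2], d[3])
      frac <- box_smooth_matrix(ind, w)
      ok <- ok & (sl != code | frac > 1 - 1e-9)
    }
    out[s, , ] <- ok
  }
  out
}

#' Per-tissue intensity statistics
#'
#' Mean, population standard deviation (divide by N) and coefficient of
#' variation for each tissue class, over the whole volume or per axial
#' slice.  Classes with no voxels in scope are omitted with a warning.
#'
#' @param vol a [volume()].
#' @param labels a [tissue_label_map()] on the same grid.
#' @param per_slice if `TRUE`, one row per (slice, tissue); otherwise one
#'   row per tissue with `scope = "volume"`.
#' @return A data.frame with columns `scope`, `tissue` (code), `tissue_name`,
#'   `n`, `mean`, `sd`, `cv_percent` (rounded to 2 decimals).
#' @export
tissue_stats <- function(vol, labels, per_slice = FALSE) {
  stopifnot_volume(vol)
  if (!inherits(labels, "tissue_label_map"))
    stop("'labels' must be a tissue_label_map", call. = FALSE)
  if (!identical(dim(vol$data), dim(labels$labels)))
    stop("volume and labels must share one grid", call. = FALSE)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  one_scope <- function(values, labs, scope) {
    rows <- lapply(0:2, function(code) {
      x <- values[labs == code]
      if (length(x) == 0L) return(NULL)
      data.frame(scope = scope, tissue = code,
                 tissue_name = TISSUE_NAMES[[as.character(code)]],
                 n = length(x), mean = mean(x), sd = pop_sd(x),
                 cv_percent = round(cv_percent(mean(x), pop_sd(x)), 2),
                 stringsAsFactors = FALSE)
    })
    present <- !vapply(rows, is.null, logical(1))
    if (!all(present))
      warning("tissue class(es) with no voxels omitted: ",
              paste(which(!present) - 1L, collapse = ", "), call. = FALSE)
    do.call(rbind, rows[present])
  }
  if (per_slice) {
    out <- do.call(rbind, lapply(seq_len(dim(vol$data)[1]), function(s)
      one_scope(as.vector(vol$data[s, , ]), as.vector(labels$labels[s, , ]),
                scope = as.character(s))))
  } else {
    out <- one_scope(as.vector(vol$data), as.vector(labels$labels), "volume")
  }
  rownames(out) <- NULL
  out
}

#' Intensity histogram over a fixed range
#'
#' Equal-width bins over an explicit range so histograms of different images
#' are comparable.  Values outside the range are clamped into the edge bins;
#' counts always sum to the number of voxels in scope.
#'
#' @param vol a [volume()].
#' @param mask optional logical array (same grid) restricting the voxels.
#' @param bins number of bins (>= 1).
#' @param range length-2 numeric; defaults to the data range in scope.
#' @return A list with `counts` (length `bins`), `edges` (length
#'   `bins + 1`) and `mids`.
#' @export
intensity_histogram <- function(vol, mask = NULL, bins = 50L, range = NULL) {
  stopifnot_volume(vol)
  bins <- as.integer(bins)
  if (bins < 1L) stop("'bins' must be >= 1", call. = FALSE)
  values <- if (is.null(mask)) as.vector(vol$data) else vol$data[mask]
  if (length(values) == 0L) stop("empty mask", call. = FALSE)
  if (is.null(range)) range <- base::range(values)
  if (range[2] <= range[1]) range[2] <- range[1] + 1
  edges <- seq(range[1], range[2], length.out = bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), bins)
  list(counts = tabulate(idx, nbins = bins), edges = edges,
       mids = (edges[-1] + edges[-length(edges)]) / 2)
}

#' Tissue-wise comparison of two volumes
#'
#' Per-tissue difference of means `mean(a) - mean(b)` on a shared label
#' map, with both sets of per-tissue statistics embedded, plus optional
#' per-slice series for mean +/- SD plots.
#'
#' @param a,b [volume()]s on the same grid (e.g. pseudo-CT vs real CT).
#' @param labels shared [tissue_label_map()].
#' @param per_slice include per-slice series for both volumes.
#' @return A list of class `comparison_report`: `differences` (data.frame
#'   with `tissue`, `tissue_name`, `mean_diff`, `mean_a`, `mean_b`, `sd_a`,
#'   `sd_b`, `cv_a`, `cv_b`), `stats_a`, `stats_b`, and optionally
#'   `per_slice_a`, `per_slice_b`.
#' @export
compare_volumes <- function(a, b, labels, per_slice = FALSE) {
  stopifnot_volume(a); stopifnot_volume(b)
  check_same_grid(a, b, "compared volumes")
  sa <- tissue_stats(a, labels)
  sb <- tissue_stats(b, labels)
  stopifnot(identical(sa$tissue, sb$tissue))
  diffs <- data.frame(
    tissue = sa$tissue, tissue_name = sa$tissue_name,
    mean_diff = sa$mean - sb$mean,
    mean_a = sa$mean, mean_b = sb$mean,
    sd_a = sa$sd, sd_b = sb$sd,
    cv_a = sa$cv_percent, cv_b = sb$cv_percent,
    stringsAsFactors = FALSE
  )
  out <- list(differences = diffs, stats_a = sa, stats_b = sb)
  if (per_slice) {
    out$per_slice_a <- tissue_stats(a, labels, per_slice = TRUE)
    out$per_slice_b <- tissue_stats(b, labels, per_slice = TRUE)
  }
  structure(out, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> per-tissue mean differences (a - b):\n")
  print(x$differences[, c("tissue_name", "mean_diff", "mean_a", "mean_b")],
        row.names = FALSE)
  invisible(x)
}
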