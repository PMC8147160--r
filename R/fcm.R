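#' Fuzzy c-means configuration
#'
#' @param k number of clusters (3 for the tissue model: air/lung, soft
#'   tissue, fat).
#' @param m fuzziness exponent, > 1.  2.0 is the conventional default.
#' @param tol convergence threshold on the maximum center movement relative
#'   to the data range.
#' @param max_iter iteration cap.
#' @param seed RNG seed; used only when clustering subsamples a very large
#'   volume (see [segment_tissues()]).
#' @param subsample_above voxel count above which clustering runs on a
#'   seeded random subsample of this size and only the final membership
#'   assignment touches every voxel.
#' @return A list of class `fcm_config`.
#' @export
fcm_config <- function(k = 3L, m = 2.0, tol = 1e-4, max_iter = 300L,
                       seed = 0L, subsample_above = 2e6) {
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  if (m <= 1) stop("fuzziness 'm' must be > 1", call. = FALSE)
  if (tol <= 0) stop("'tol' must be positive", call. = FALSE)
  if (max_iter < 1L) stop("'max_iter' must be >= 1", call. = FALSE)
  structure(list(k = k, m = m, tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), subsample_above = subsample_above),
            class = "fcm_config")
}

## Membership update for given centers: u_ij = 1 / sum_l (d_ij/d_il)^(2/(m-1)).
## Exact-zero distances get full membership on (ties: shared among) the
## coincident clusters.
fcm_memberships <- function(values, centers, m) {
  n <- length(values)
  k <- length(centers)
  d2 <- outer(values, centers, function(x, c) (x - c)^2)
  zero <- d2 == 0
  any_zero <- rowSums(zero) > 0
  p <- 1 / (m - 1)
  inv <- d2^(-p)                       # (1/d^2)^(1/(m-1))
  u <- inv / rowSums(inv)
  if (any(any_zero)) {
    z <- which(any_zero)
    u[z, ] <- zero[z, , drop = FALSE] / rowSums(zero[z, , drop = FALSE])
  }
  u
}

#' Fuzzy c-means clustering of scalar intensities
#'
#' Standard FCM alternating minimization of
#' `J = sum_ij u_ij^m (x_i - c_j)^2`: memberships
#' `u_ij` proportional to `(1/d_ij)^(2/(m-1))`, centers the
#' membership-weighted means `c_j = sum_i u_ij^m x_i / sum_i u_ij^m`.
#' Initial centers sit at evenly spaced quantiles `(2j-1)/(2k)` of the
#' intensity distribution, so a given input always yields the same
#' partition.  Iteration stops when the maximum center movement, relative to
#' the data range, falls below `cfg$tol`, or after `cfg$max_iter` rounds.
#'
#' @param values finite numeric vector with at least `k` distinct values.
#' @param cfg an [fcm_config()].
#' @return A list of class `fuzzy_partition`: `memberships` (n x k matrix,
#'   rows summing to 1), `centers` (length k, in initialization order),
#'   `m`, `objective_history` (non-increasing), `iterations`, `converged`.
#' @export
fcm_cluster <- function(values, cfg = fcm_config()) {
  values <- as.numeric(values)
  if (anyNA(values) || !all(is.finite(values)))
    stop("'values' must be finite", call. = FALSE)
  k <- cfg$k
  if (length(unique(values)) < k)
    stop("need at least k distinct values for k clusters", call. = FALSE)
  rng <- range(values)
  span <- max(rng[2] - rng[1], .Machine$double.eps)
  centers <- as.numeric(stats::quantile(values, probs = (2 * seq_len(k) - 1) /
                                          (2 * k), names = FALSE, type = 7))
  ## coincident initial quantiles (heavily tied data): spread across range
  if (anyDuplicated(centers))
    centers <- centers + span * 1e-6 * (seq_len(k) - (k + 1) / 2)
  history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  u <- NULL
  for (iter in seq_len(cfg$max_iter)) {
    u <- fcm_memberships(values, centers, cfg$m)
    um <- u^cfg$m
    new_centers <- as.numeric(crossprod(um, values)) / colSums(um)
    ## guard: empty cluster (cannot occur with finite d, but keep finite)
    bad <- !is.finite(new_centers)
    if (any(bad)) new_centers[bad] <- centers[bad]
    d2 <- outer(values, new_centers, function(x, c) (x - c)^2)
    history <- c(history, sum(um * d2))
    moved <- max(abs(new_centers - centers)) / span
    centers <- new_centers
    if (moved < cfg$tol) { converged <- TRUE; break }
  }
  u <- fcm_memberships(values, centers, cfg$m)
  structure(list(memberships = u, centers = centers, m = cfg$m,
                 objective_history = history, iterations = iter,
                 converged = converged),
            class = "fuzzy_partition")
}

#' Harden a fuzzy partition to per-voxel cluster indices
#'
#' Argmax membership; ties break toward the lowest cluster index.
#'
#' @param p a `fuzzy_partition` (or any matrix of memberships).
#' @return Integer vector of 1-based cluster indices.
#' @export
harden_partition <- function(p) {
  u <- if (inherits(p, "fuzzy_partition")) p$memberships else as.matrix(p)
  max.col(u, ties.method = "first")
}

#' Segment an MRI volume into three tissue classes
#'
#' Clusters all voxel intensities (including exterior background air, which
#' falls into the air/lung class) with fuzzy c-means, hardens the partition,
#' and maps clusters to tissue codes by ascending center intensity: lowest
#' -> air/lung (0), middle -> soft tissue (1), highest -> fat (2).  This
#' ordering matches the T1-weighted contrast of both targeted scanners.  For
#' volumes above `cfg$subsample_above` voxels, cluster centers are fit on a
#' seeded random subsample and every voxel is then assigned from the final
#' centers.
#'
#' @param vol an MRI-modality [volume()].
#' @param cfg an [fcm_config()] with `k = 3`.
#' @param per_slice if `TRUE`, cluster each axial slice independently
#'   (default clusters the whole volume at once).
#' @return A [tissue_label_map()] on the volume's grid.
#' @export
segment_tissues <- function(vol, cfg = fcm_config(), per_slice = FALSE) {
  stopifnot_volume(vol)
  if (cfg$k != 3L)
    stop("tissue segmentation uses k = 3 (air/lung, soft tissue, fat)",
         call. = FALSE)
  seg_one <- function(values) {
    if (length(unique(values)) < 3L)
      stop("degenerate volume: fewer than 3 distinct intensities",
           call. = FALSE)
    n <- length(values)
    if (n > cfg$subsample_above) {
      idx <- with_seed(cfg$seed,
                       sample.int(n, size = as.integer(cfg$subsample_above)))
      part <- fcm_cluster(values[idx], cfg)
      centers <- part$centers
      u <- fcm_memberships(values, centers, cfg$m)
      hard <- max.col(u, ties.method = "first")
    } else {
      part <- fcm_cluster(values, cfg)
      centers <- part$centers
      hard <- harden_partition(part)
    }
    ## tissue code by ascending center intensity
    code_of_cluster <- integer(3L)
    code_of_cluster[order(centers)] <- 0:2
    code_of_cluster[hard]
  }
  lab <- array(0L, dim = dim(vol$data))
  if (per_slice) {
    for (s in seq_len(dim(vol$data)[1]))
      lab[s, , ] <- seg_one(as.vector(vol$data[s, , ]))
  } else {
    lab[] <- seg_one(as.vector(vol$data))
  }
  tissue_label_map(lab, spacing = vol$spacing)
}
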