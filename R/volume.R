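#' @keywords internal
"_PACKAGE"

VOLUME_MODALITIES <- c("MRI", "CT", "PSEUDO_CT", "MAP")

default_units <- function(modality) {
  switch(modality,
    MRI = "a.u.",
    CT = "HU",
    PSEUDO_CT = "HU",
    MAP = "ratio"
  )
}

#' Construct a volumetric image
#'
#' A `volume` is a 3-D scalar grid indexed `[slice, row, col]` (axis 1 is the
#' slice/longitudinal axis; all per-slice operations in this package iterate
#' over it), with per-axis voxel spacing in millimetres and a modality tag.
#' A 2-D matrix is accepted and stored as a single-slice volume.
#'
#' @param data numeric array; 3-D `(slice, row, col)`, or a 2-D matrix which
#'   becomes one slice.  All values must be finite.  Stored as doubles even
#'   when the source is integer, because the normalization method divides
#'   images voxelwise.
#' @param spacing numeric length-3, millimetres per axis in `(slice, row,
#'   col)` order; strictly positive.
#' @param modality one of `"MRI"`, `"CT"`, `"PSEUDO_CT"`, `"MAP"`.
#' @param units free-text unit label; defaults to `"a.u."` for MRI, `"HU"`
#'   for CT and pseudo-CT, `"ratio"` for maps.
#' @return An object of class `volume` with fields `data`, `spacing`,
#'   `modality`, `units`.
#' @export
#' @examples
#' v <- volume(array(0, c(2, 4, 4)), spacing = c(3, 1.5, 1.5))
#' dim(v)
volume <- function(data, spacing = c(1, 1, 1), modality = "MRI",
                   units = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array or a 2-D matrix", call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume values must all be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive reals (mm)", call. = FALSE)
  modality <- match.arg(modality, VOLUME_MODALITIES)
  if (is.null(units)) units <- default_units(modality)
  storage.mode(data) <- "double"
  structure(
    list(data = data, spacing = spacing, modality = modality,
         units = as.character(units)),
    class = "volume"
  )
}

#' @export
dim.volume <- function(x) dim(x$data)

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %s [%s]  %d x %d x %d voxels, spacing %s mm\n",
              x$modality, x$units, d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "volume")

stopifnot_volume <- function(x, name = deparse(substitute(x))) {
  if (!is_volume(x)) stop(sprintf("'%s' must be a volume", name), call. = FALSE)
  invisible(x)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("%s must share one grid: %s vs %s", what,
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

#' Construct a tissue label map
#'
#' Hard per-voxel tissue codes on the same grid as the segmented volume:
#' 0 = air/lung, 1 = soft tissue, 2 = fat.
#'
#' @param labels integer array (3-D, or 2-D for a single slice) with values
#'   in `{0, 1, 2}`.
#' @param spacing voxel spacing in mm, as for [volume()].
#' @return An object of class `tissue_label_map` with fields `labels` and
#'   `spacing`.
#' @export
tissue_label_map <- function(labels, spacing = c(1, 1, 1)) {
  if (is.matrix(labels)) labels <- array(labels, dim = c(1L, dim(labels)))
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3-D array or 2-D matrix", call. = FALSE)
  if (anyNA(labels) || !all(labels %in% 0:2))
    stop("tissue labels must all be in {0, 1, 2}", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing)),
            class = "tissue_label_map")
}

#' @export
dim.tissue_label_map <- function(x) dim(x$labels)

#' @export
print.tissue_label_map <- function(x, ...) {
  d <- dim(x$labels)
  tab <- tabulate(as.vector(x$labels) + 1L, nbins = 3L)
  cat(sprintf("<tissue_label_map> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  air/lung: %d, soft tissue: %d, fat: %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

TISSUE_NAMES <- c(`0` = "air_lung", `1` = "soft_tissue", `2` = "fat")

#' Read a volumetric image from disk
#'
#' Reads a NIfTI-1 file or a DICOM series directory into a [volume()].  The
#' slice axis is stored as axis 1 and spacing is taken from the header.  For
#' DICOM series, files are sorted by slice position along the normal and the
#' rescale slope/intercept is applied, so CT volumes come back in Hounsfield
#' units.
#'
#' @param path file path (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom_dir"`.
#' @param modality modality tag to attach; defaults to `"MRI"` for NIfTI and
#'   `"CT"` for DICOM.
#' @param units unit label; defaults by modality.
#' @return A [volume()].
#' @export
read_volume <- function(path, format = c("nifti", "dicom_dir"),
                        modality = NULL, units = NULL) {
  format <- match.arg(format)
  if (format == "nifti") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 2L) {
      arr <- array(as.numeric(img), dim = c(1L, d))
      sp <- c(1, RNifti::pixdim(img))
    } else if (length(d) == 3L) {
      arr <- array(as.numeric(img), dim = d)
      sp <- RNifti::pixdim(img)
    } else {
      stop("expected a 2-D or 3-D NIfTI image, got ", length(d), " dims",
           call. = FALSE)
    }
    if (is.null(modality)) modality <- "MRI"
    volume(arr, spacing = sp, modality = modality, units = units)
  } else {
    if (is.null(modality)) modality <- "CT"
    read_dicom_series(path, modality = modality, units = units)
  }
}

#' Write a volume to a NIfTI-1 file
#'
#' The voxel grid and spacing survive a write/read round trip to float32
#' precision.  Modality and units are not part of the NIfTI header and must
#' be re-attached on read.
#'
#' @param vol a [volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype on-disk datatype, default `"float"` (32-bit).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "float") {
  stopifnot_volume(vol)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir,
                             call. = FALSE)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a tissue label map to NIfTI
#' @param labels a [tissue_label_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  img <- RNifti::asNifti(labels$labels)
  RNifti::pixdim(img) <- labels$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a tissue label map from NIfTI
#' @param path NIfTI file written by [write_label_map()].
#' @return A [tissue_label_map()].
#' @export
read_label_map <- function(path) {
  v <- read_volume(path, "nifti")
  tissue_label_map(array(as.integer(round(v$data)), dim = dim(v$data)),
                   spacing = v$spacing)
}

## Evaluate an expression with a temporarily seeded RNG, restoring the
## caller's RNG state afterwards.  All stochastic operations in the package
## funnel through this so that user-level seeds compose.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
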