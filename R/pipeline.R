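#' Default end-to-end pipeline configuration
#'
#' One document mirroring the per-module configurations, consumed by
#' [run_pipeline()].  Every stage can be toggled; seeds for all stochastic
#' stages derive from the single `seed` unless overridden.
#'
#' @param out_dir output directory.
#' @param seed global seed.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(out_dir = "mrpct_run", seed = 0L) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, segment = TRUE, normalize = TRUE,
                  register = TRUE, pairs = TRUE, train = TRUE,
                  convert = TRUE, evaluate = TRUE),
    inputs = list(mri = NULL, ct = NULL),   # used when simulate is off
    simulate = list(preset = "chest", shape = c(12L, 128L, 128L),
                    bias = list(type = "gaussian_blobs", amplitude = 0.3,
                                scale = 40), noise_sd = 5),
    segment = list(m = 2.0, tol = 1e-4, max_iter = 300L),
    normalize = list(bulk = c(air_lung = 18, soft_tissue = 65, fat = 149),
                     width = 10L),
    register = list(enabled_when_simulated = FALSE, bins = 50L,
                    samples = 2000L,
                    free = c("r1", "t2", "t3")),
    pairs = list(slices = c(2L, 4L, 6L, 8L), validation_slices = 10L,
                 counts = c(air_lung = 25L, soft_tissue = 50L, fat = 25L),
                 block_px = 40L),
    train = list(kernel_sizes = c(7L, 5L, 5L), channels = c(8L, 8L, 1L),
                 dsn_weights = c(0.3, 0.3), epochs = 10L,
                 n_patches_per_template = 250L,
                 n_val_patches_per_template = 50L,
                 batch_size = 128L, learning_rate = 0.01, momentum = 0.9),
    convert = list(stride = 18L),
    evaluate = list(per_slice = TRUE)
  ), class = "run_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Values present in the file override the defaults from
#' [default_run_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_run_config()), user)
  class(cfg) <- "run_config"
  cfg
}

pipeline_log <- function(logfile, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 sprintf(fmt, ...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the end-to-end pseudo-CT pipeline
#'
#' Executes the enabled stages in order -- simulate (or ingest) -> segment
#' -> normalize -> register -> extract pairs -> train -> convert ->
#' evaluate -- writing each artifact plus a JSON provenance record (stage
#' inputs, configuration, seed, package version, md5 checksums) under
#' `cfg$out_dir`.  With identical configuration the deterministic stages
#' reproduce identical artifacts.
#'
#' When the simulate stage is on, the phantom's CT is already voxel-aligned
#' with its MRI, so the registration stage defaults to a pass-through
#' (enable `register$enabled_when_simulated` to exercise it anyway).
#'
#' @param cfg a `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @return Invisibly, the manifest: a named list of produced artifact
#'   paths (also written as `manifest.json`).
#' @export
run_pipeline <- function(cfg = default_run_config()) {
  if (!inherits(cfg, "run_config")) stop("'cfg' must be a run_config",
                                         call. = FALSE)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  manifest <- list()
  provenance <- list(package_version =
                       as.character(utils::packageVersion("mrpct")),
                     seed = cfg$seed, stages_run = character(0))
  t_start <- Sys.time()
  add_artifact <- function(name, path) {
    manifest[[name]] <<- path
    invisible(path)
  }
  st <- cfg$stages
  mri <- ct <- truth <- NULL

  if (isTRUE(st$simulate)) {
    pipeline_log(logfile, "simulate: %s phantom %s",
                 cfg$simulate$preset,
                 paste(cfg$simulate$shape, collapse = "x"))
    pcfg <- phantom_config(cfg$simulate$preset, cfg$simulate$shape,
                           bias = cfg$simulate$bias,
                           noise_sd = cfg$simulate$noise_sd,
                           seed = cfg$seed)
    truth <- make_torso_phantom(pcfg)
    mri <- truth$mri; ct <- truth$ct
    add_artifact("mri", write_volume(mri, file.path(out_dir, "mri.nii.gz")))
    add_artifact("ct", write_volume(ct, file.path(out_dir, "ct.nii.gz")))
    add_artifact("true_labels",
                 write_label_map(truth$labels,
                                 file.path(out_dir, "true_labels.nii.gz")))
    add_artifact("bias_field",
                 write_volume(truth$bias_field,
                              file.path(out_dir, "bias_field.nii.gz")))
    provenance$stages_run <- c(provenance$stages_run, "simulate")
  } else if (!is.null(cfg$inputs$mri)) {
    mri <- read_volume(cfg$inputs$mri, "nifti", modality = "MRI")
    if (!is.null(cfg$inputs$ct))
      ct <- read_volume(cfg$inputs$ct, "nifti", modality = "CT")
  }

  labels <- NULL
  if (isTRUE(st$segment)) {
    if (is.null(mri)) stop("segment stage needs an MRI input",
                           call. = FALSE)
    pipeline_log(logfile, "segment: FCM k=3 (m=%.2f)", cfg$segment$m)
    labels <- segment_tissues(mri, fcm_config(m = cfg$segment$m,
                                              tol = cfg$segment$tol,
                                              max_iter = cfg$segment$max_iter,
                                              seed = cfg$seed))
    add_artifact("labels",
                 write_label_map(labels, file.path(out_dir,
                                                   "labels.nii.gz")))
    provenance$stages_run <- c(provenance$stages_run, "segment")
  }

  corrected <- NULL
  if (isTRUE(st$normalize)) {
    if (is.null(mri)) stop("normalize stage needs an MRI input",
                           call. = FALSE)
    pipeline_log(logfile, "normalize: width %d", cfg$normalize$width)
    bulk <- do.call(bulk_intensities, as.list(cfg$normalize$bulk))
    norm <- normalize_mri(mri, bulk, width = cfg$normalize$width,
                          labels = labels)
    corrected <- norm$corrected
    if (is.null(labels)) labels <- norm$labels
    add_artifact("corrected",
                 write_volume(corrected,
                              file.path(out_dir, "mri_corrected.nii.gz")))
    add_artifact("shading",
                 write_volume(norm$shading$map,
                              file.path(out_dir, "shading_map.nii.gz")))
    provenance$stages_run <- c(provenance$stages_run, "normalize")
  }

  ct_reg <- ct
  if (isTRUE(st$register) && !is.null(ct) &&
      (!isTRUE(st$simulate) || isTRUE(cfg$register$enabled_when_simulated))) {
    pipeline_log(logfile, "register: rigid MI (%d bins, %d samples)",
                 cfg$register$bins, cfg$register$samples)
    ref <- if (!is.null(corrected)) corrected else mri
    tr <- rigid_register(ref, ct,
                         mattes_config(cfg$register$bins,
                                       cfg$register$samples,
                                       seed = cfg$seed),
                         free = cfg$register$free)
    ct_reg <- resample(ct, tr, ref)
    add_artifact("transform",
                 write_transform(tr, file.path(out_dir, "transform.json")))
    add_artifact("ct_registered",
                 write_volume(ct_reg, file.path(out_dir,
                                                "ct_registered.nii.gz")))
    provenance$stages_run <- c(provenance$stages_run, "register")
  }

  pairs <- val_pairs <- NULL
  if (isTRUE(st$pairs)) {
    if (is.null(corrected) || is.null(ct_reg) || is.null(labels))
      stop("pair extraction needs corrected MRI, registered CT and labels",
           call. = FALSE)
    pipeline_log(logfile, "pairs: slices %s",
                 paste(cfg$pairs$slices, collapse = ","))
    pairs <- extract_pairs(corrected, ct_reg, labels,
                           slices = cfg$pairs$slices,
                           counts = cfg$pairs$counts, role = "training")
    val_pairs <- extract_pairs(corrected, ct_reg, labels,
                               slices = cfg$pairs$validation_slices,
                               counts = cfg$pairs$counts,
                               role = "validation")
    add_artifact("pairs", write_pairs(pairs, file.path(out_dir,
                                                       "pairs.csv")))
    add_artifact("val_pairs",
                 write_pairs(val_pairs, file.path(out_dir,
                                                  "pairs_validation.csv")))
    provenance$stages_run <- c(provenance$stages_run, "pairs")
  }

  model <- NULL
  if (isTRUE(st$train)) {
    if (is.null(pairs)) stop("training needs extracted pairs",
                             call. = FALSE)
    tc <- cfg$train
    pipeline_log(logfile, "train: %d epochs, channels %s", tc$epochs,
                 paste(tc$channels, collapse = "/"))
    templates <- build_templates(pairs, block_px = cfg$pairs$block_px)
    val_templates <- build_templates(val_pairs,
                                     block_px = cfg$pairs$block_px)
    train_set <- crop_patches(templates, tc$n_patches_per_template,
                              seed = cfg$seed)
    val_set <- crop_patches(val_templates, tc$n_val_patches_per_template,
                            seed = cfg$seed + 1L)
    model <- build_model(model_spec(tc$kernel_sizes, tc$channels,
                                    tc$dsn_weights), seed = cfg$seed)
    model <- train_model(model, train_set, val_set,
                         train_config(batch_size = tc$batch_size,
                                      learning_rate = tc$learning_rate,
                                      momentum = tc$momentum,
                                      epochs = tc$epochs,
                                      seed = cfg$seed))
    add_artifact("model", save_model(model, file.path(out_dir, "model")))
    provenance$stages_run <- c(provenance$stages_run, "train")
  }

  pct <- NULL
  if (isTRUE(st$convert)) {
    if (is.null(model) || is.null(corrected))
      stop("conversion needs a trained model and corrected MRI",
           call. = FALSE)
    pipeline_log(logfile, "convert: stride %d", cfg$convert$stride)
    pct <- predict_volume(model, corrected, stride = cfg$convert$stride)
    add_artifact("pseudo_ct",
                 write_volume(pct, file.path(out_dir,
                                             "pseudo_ct.nii.gz")))
    provenance$stages_run <- c(provenance$stages_run, "convert")
  }

  if (isTRUE(st$evaluate) && !is.null(pct) && !is.null(ct_reg) &&
      !is.null(labels)) {
    pipeline_log(logfile, "evaluate: pseudo-CT vs CT")
    rep <- compare_volumes(pct, ct_reg, labels,
                           per_slice = isTRUE(cfg$evaluate$per_slice))
    eval_path <- file.path(out_dir, "evaluation.json")
    jsonlite::write_json(list(differences = rep$differences,
                              stats_pseudo_ct = rep$stats_a,
                              stats_ct = rep$stats_b),
                         eval_path, dataframe = "rows", digits = NA)
    utils::write.csv(rep$differences,
                     file.path(out_dir, "evaluation.csv"),
                     row.names = FALSE)
    add_artifact("evaluation", eval_path)
    add_artifact("evaluation_csv", file.path(out_dir, "evaluation.csv"))
    provenance$stages_run <- c(provenance$stages_run, "evaluate")
  }

  provenance$elapsed_sec <- as.numeric(Sys.time() - t_start, units = "secs")
  provenance$config <- unclass(cfg)
  files <- unlist(manifest[vapply(manifest, function(p)
    length(p) == 1 && file.exists(p) && !dir.exists(p), logical(1))])
  provenance$checksums <- if (length(files))
    as.list(tools::md5sum(files)) else list()
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  pipeline_log(logfile, "done: %d artifacts in %s", length(manifest),
               out_dir)
  invisible(manifest)
}
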