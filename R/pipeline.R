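#' Experiment configuration
#'
#' Single configuration object driving the whole experiment: phantom cohort,
#' degradation, network, training, feature extraction and stability
#' analysis. All stage seeds derive from `seed`.
#'
#' The defaults define the desk-scale study conditions used throughout the
#' package's analyses: 64x64 phantoms with one lesion each and mild Rician
#' baseline noise, a cohort of 440 images (about 300 train / 74 validation /
#' 66 test under the default fractions), a depth-3 residual U-Net, and at
#' least 40 test lesions for the stability statistics. When `unet` or
#' `train` is not supplied, mode-appropriate defaults are chosen: the
#' denoising task needs capacity at the finest scale (8 base channels,
#' 8 epochs), while the resampling correction is spatially smooth and a
#' lighter network suffices (4 base channels, 10 epochs).
#'
#' @param phantom a [phantom_config()].
#' @param degradation a [degradation_config()].
#' @param unet a [unet_spec()].
#' @param train a [train_config()].
#' @param extraction an [extraction_settings()].
#' @param n_images cohort size.
#' @param n_test_lesions minimum lesions in the test partition.
#' @param reconstruction `"unet"` (train and apply the restoration model) or
#'   `"passthrough"` (identity; the restored condition equals its input).
#' @param ccc_threshold stability threshold on Lin's CCC.
#' @param seed master seed; overrides the seeds of the component configs.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_config(matrix_size = 64L,
                                                       n_lesions = 1L,
                                                       lesion_radius_range = c(3, 6),
                                                       baseline_noise_sigma = 0.5),
                              degradation = degradation_config("nex"),
                              unet = NULL,
                              train = NULL,
                              extraction = extraction_settings(),
                              n_images = 440L,
                              n_test_lesions = 40L,
                              reconstruction = c("unet", "passthrough"),
                              ccc_threshold = 0.85,
                              seed = 1L) {
  reconstruction <- match.arg(reconstruction)
  if (is.null(unet))
    unet <- if (identical(degradation$mode, "nex"))
      unet_spec(depth = 3L, base_channels = 8L)
    else unet_spec(depth = 3L, base_channels = 4L)
  if (is.null(train))
    train <- if (identical(degradation$mode, "nex"))
      train_config(epochs = 8L) else train_config(epochs = 10L)
  stopifnot(inherits(phantom, "phantom_config"),
            inherits(degradation, "degradation_config"),
            inherits(unet, "unet_spec"), inherits(train, "train_config"),
            inherits(extraction, "extraction_settings"))
  seed <- as.integer(seed)
  phantom$seed <- seed
  degradation$seed <- seed + 11L
  train$seed <- seed + 17L
  cfg <- list(phantom = phantom, degradation = degradation, unet = unet,
              train = train, extraction = extraction,
              n_images = as.integer(n_images),
              n_test_lesions = as.integer(n_test_lesions),
              reconstruction = reconstruction,
              ccc_threshold = ccc_threshold, seed = seed)
  cfg$id <- config_id(lapply(cfg, function(x)
    if (is.list(x)) unclass(x) else x))
  structure(cfg, class = "experiment_config")
}

#' Run the full stability experiment
#'
#' Executes, in order: cohort generation, fast-acquisition degradation,
#' restoration-model training (unless `reconstruction = "passthrough"`),
#' application of the model to held-out test images, image-quality grading
#' (PSNR/SSIM of fast and restored images against the reference), radiomic
#' feature extraction for every test lesion under the reference, fast and
#' restored conditions, per-feature stability statistics for both
#' comparisons, the per-class restoration summary, and Bland-Altman
#' agreement of the bundled predictive-model scores. Deterministic given the
#' master seed (single-threaded numerics).
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, every stage output is
#'   persisted (CSV/JSON) together with a run manifest keyed by the
#'   configuration id, so a finished run can be inspected or reused without
#'   recomputation.
#' @param verbose print stage progress.
#' @return a list of class `experiment_result` with elements `cohort`
#'   (manifest only), `model` (history and manifest), `quality`, `features`,
#'   `stability` (both comparisons), `summary`, `models` (per-model
#'   Bland-Altman for fast and restored scores), and `config`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  persist <- !is.null(out_dir)
  if (persist) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say("stage 1/7: cohort (%d images)", config$n_images)
  cohort <- generate_cohort(config$phantom, config$n_images,
                            config$n_test_lesions)
  test_imgs <- cohort_subset(cohort, "test")

  say("stage 2/7: degradation (%s)", config$degradation$mode)
  fast_imgs <- lapply(seq_along(test_imgs), function(i)
    degrade(test_imgs[[i]], config$degradation,
            seed = config$degradation$seed + 524287L + i))

  model <- NULL
  if (config$reconstruction == "unet") {
    say("stage 3/7: training (%d epochs)", config$train$epochs)
    model <- train_model(cohort, config$degradation, config$unet,
                         config$train, verbose = verbose)
    dl_imgs <- lapply(fast_imgs, function(im) apply_model(model, im))
  } else {
    say("stage 3/7: reconstruction = passthrough")
    dl_imgs <- lapply(fast_imgs, function(im)
      rewrap_degraded(im, pixels_of(im), label = "dl"))
  }

  say("stage 4/7: image quality")
  imax <- config$phantom$intensity_max
  quality <- do.call(rbind, lapply(seq_along(test_imgs), function(i) {
    ref <- pixels_of(test_imgs[[i]])
    data.frame(image = i,
               psnr_fast = psnr(ref, pixels_of(fast_imgs[[i]]), imax),
               psnr_dl = psnr(ref, pixels_of(dl_imgs[[i]]), imax),
               ssim_fast = ssim(ref, pixels_of(fast_imgs[[i]]), imax),
               ssim_dl = ssim(ref, pixels_of(dl_imgs[[i]]), imax))
  }))

  say("stage 5/7: radiomics (3 conditions)")
  features <- extract_feature_table(
    list(reference = test_imgs, fast = fast_imgs, dl = dl_imgs),
    config$extraction)

  say("stage 6/7: stability statistics")
  stab_fast <- paired_feature_stats(features, "fast_vs_ref",
                                    config$ccc_threshold)
  stab_dl <- paired_feature_stats(features, "dl_vs_ref",
                                  config$ccc_threshold)
  summary_tab <- restoration_summary(stab_fast, stab_dl)

  say("stage 7/7: predictive-model agreement")
  model_res <- lapply(predictive_model_fixtures(), function(spec) {
    spec <- standardize_from_reference(spec, features)
    s_ref <- model_scores(spec, features, "reference")
    list(name = spec$name,
         fast = bland_altman(s_ref, model_scores(spec, features, "fast")),
         dl = bland_altman(s_ref, model_scores(spec, features, "dl")))
  })

  res <- structure(list(cohort = cohort$manifest,
                        model = if (!is.null(model))
                          list(history = model$history,
                               manifest = model$manifest) else NULL,
                        quality = quality, features = features,
                        stability = list(fast_vs_ref = stab_fast,
                                         dl_vs_ref = stab_dl),
                        summary = summary_tab, models = model_res,
                        config = config),
                   class = "experiment_result")
  if (persist) write_experiment_outputs(res, out_dir)
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  ov <- x$summary[x$summary$class == "overall", ]
  cat(sprintf(paste0("<experiment_result: %d/%d features unstable (fast), ",
                     "%d/%d (restored), %d restored>\n"),
              ov$unstable_fast, ov$n, ov$unstable_dl, ov$n, ov$restored))
  invisible(x)
}

write_experiment_outputs <- function(res, out_dir) {
  wcsv <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(res$quality, "quality.csv")
  wcsv(res$features, "features.csv")
  wcsv(res$stability$fast_vs_ref, "stability_fast_vs_ref.csv")
  wcsv(res$stability$dl_vs_ref, "stability_dl_vs_ref.csv")
  wcsv(res$summary, "summary_by_class.csv")
  if (!is.null(res$model)) wcsv(res$model$history, "training_history.csv")
  ba <- lapply(res$models, function(m) list(
    name = m$name,
    fast = m$fast[c("mean_difference", "sd_difference", "loa_lower",
                    "loa_upper", "p_value")],
    dl = m$dl[c("mean_difference", "sd_difference", "loa_lower",
                "loa_upper", "p_value")]))
  manifest <- list(config_id = res$config$id, seed = res$config$seed,
                   cohort = res$cohort, bland_altman = ba)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(NULL)
}
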