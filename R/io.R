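# Thin I/O layer: images as NIfTI (RNifti) or PNG, masks alongside,
# experiment configuration from YAML/JSON.

#' Write a phantom image (and its masks) to NIfTI files
#'
#' @param image a `phantom_image`.
#' @param path output file for the pixel data (`.nii` / `.nii.gz`); masks go
#'   to `<path>_mask<k>.nii` siblings.
#' @return invisibly, the paths written.
#' @export
write_image_nifti <- function(image, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI output", call. = FALSE)
  stopifnot(inherits(image, "phantom_image"))
  RNifti::writeNifti(RNifti::asNifti(image$pixels), path)
  paths <- path
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  for (k in seq_along(image$lesion_masks)) {
    mp <- sprintf("%s_mask%d.nii", stem, k)
    RNifti::writeNifti(RNifti::asNifti(image$lesion_masks[[k]] * 1), mp)
    paths <- c(paths, mp)
  }
  invisible(paths)
}

#' Read a 2D image from a NIfTI file
#'
#' @param path NIfTI file.
#' @return a numeric matrix.
#' @export
read_image_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI input", call. = FALSE)
  x <- RNifti::readNifti(path)
  m <- as.array(x)
  if (length(dim(m)) > 2) m <- m[, , 1]
  matrix(as.numeric(m), nrow(m), ncol(m))
}

#' Write an image or mask as 8-bit PNG
#'
#' Intensities are scaled by `max_value` into `[0, 1]`.
#'
#' @param image numeric or logical matrix, or `phantom_image`.
#' @param path output path.
#' @param max_value intensity scale (defaults to the image maximum).
#' @export
write_image_png <- function(image, path, max_value = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for PNG output", call. = FALSE)
  x <- pixels_of(image)
  if (is.logical(x)) x <- x * 1
  if (is.null(max_value)) max_value <- max(x, 1e-12)
  png::writePNG(pmin(pmax(x / max_value, 0), 1), path)
  invisible(path)
}

#' Read an experiment configuration from a YAML or JSON file
#'
#' The file holds scalar overrides grouped by section (`phantom`,
#' `degradation`, `unet`, `train`, `extraction`, and top-level `n_images`,
#' `n_test_lesions`, `reconstruction`, `ccc_threshold`, `seed`); omitted
#' entries keep package defaults. The schema is validated by the component
#' constructors before any stage runs.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build <- function(ctor, section) do.call(ctor, as.list(raw[[section]] %||% list()))
  args <- list(phantom = build(phantom_config, "phantom"),
               degradation = build(degradation_config, "degradation"),
               unet = build(unet_spec, "unet"),
               train = build(train_config, "train"),
               extraction = build(extraction_settings, "extraction"))
  for (nm in c("n_images", "n_test_lesions", "reconstruction",
               "ccc_threshold", "seed"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  do.call(experiment_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
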