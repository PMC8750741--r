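#' Wavelet-based image-quality feature
#'
#' One-level 2D Haar decomposition of the mean-centred region; the feature
#' is the ratio of detail-subband energy (LH + HL + HH) to
#' approximation-subband (LL) energy. High-frequency content — noise in
#' particular — loads the detail bands, so the ratio rises with noise and is
#' 0 for a constant region (mean centring removes the DC offset that would
#' otherwise dominate LL).
#'
#' `scope = "global"` analyses the whole image. `scope = "local"` analyses
#' the VOI only: within the lesion bounding box, only 2x2 Haar blocks lying
#' entirely inside the mask contribute, so the lesion *boundary* — structure,
#' not image quality — is excluded and the feature reads the noise content
#' of the lesion interior.
#'
#' @param image numeric matrix or `phantom_image`.
#' @param mask logical matrix (required for `scope = "local"`).
#' @param scope `"local"` or `"global"`.
#' @return the energy ratio (0 when there is no detail energy; may be `Inf`
#'   for pathological pure-Nyquist regions with no residual low-frequency
#'   energy).
#' @export
iq_wavelet <- function(image, mask = NULL, scope = c("local", "global")) {
  scope <- match.arg(scope)
  image <- pixels_of(image)
  if (scope == "global") {
    region <- trim_even(image)
    if (nrow(region) < 2 || ncol(region) < 2)
      stop("region too small for the wavelet support (needs >= 2x2)",
           call. = FALSE)
    keep <- matrix(TRUE, nrow(region) / 2, ncol(region) / 2)
    region <- region - mean(region)
  } else {
    mask <- as_mask(mask)
    ri <- range(which(rowSums(mask) > 0))
    ci <- range(which(colSums(mask) > 0))
    region <- image[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
    sub_mask <- mask[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
    region <- trim_even(region)
    sub_mask <- trim_even(sub_mask)
    if (nrow(region) < 2 || ncol(region) < 2)
      stop("region too small for the wavelet support (needs >= 2x2)",
           call. = FALSE)
    ev_i <- seq(1, nrow(region), 2); ev_j <- seq(1, ncol(region), 2)
    keep <- sub_mask[ev_i, ev_j, drop = FALSE] &
      sub_mask[ev_i + 1, ev_j, drop = FALSE] &
      sub_mask[ev_i, ev_j + 1, drop = FALSE] &
      sub_mask[ev_i + 1, ev_j + 1, drop = FALSE]
    if (!any(keep))
      stop("region too small for the wavelet support (no 2x2 block inside the mask)",
           call. = FALSE)
    # centre on the pixels of the contributing blocks only
    contrib <- matrix(FALSE, nrow(region), ncol(region))
    contrib[ev_i, ev_j] <- keep; contrib[ev_i + 1, ev_j] <- keep
    contrib[ev_i, ev_j + 1] <- keep; contrib[ev_i + 1, ev_j + 1] <- keep
    region <- region - mean(region[contrib])
  }
  a <- region[seq(1, nrow(region), 2), seq(1, ncol(region), 2), drop = FALSE]
  b <- region[seq(1, nrow(region), 2), seq(2, ncol(region), 2), drop = FALSE]
  cc <- region[seq(2, nrow(region), 2), seq(1, ncol(region), 2), drop = FALSE]
  d <- region[seq(2, nrow(region), 2), seq(2, ncol(region), 2), drop = FALSE]
  ll <- ((a + b + cc + d) / 2)[keep]
  lh <- ((a - b + cc - d) / 2)[keep]
  hl <- ((a + b - cc - d) / 2)[keep]
  hh <- ((a - b - cc + d) / 2)[keep]
  detail <- sum(lh^2) + sum(hl^2) + sum(hh^2)
  approx <- sum(ll^2)
  if (detail == 0) return(0)
  detail / approx
}

#' Extract the full 104-feature vector for one lesion on one image
#'
#' First-order statistics are computed on the raw masked intensities;
#' GLCM/GLRLM/GLSZM/GLDM/NGTDM on the discretized masked image (fixed bin
#' width by default) following the standard matrix definitions; the two IQ
#' wavelet features via [iq_wavelet()]. Deterministic. Degenerate
#' single-gray-level regions yield the conventional defined values (zero
#' variance and entropy, normalised non-uniformities of 1), not errors.
#'
#' @param image a `phantom_image` or numeric matrix.
#' @param mask logical matrix with at least 9 pixels, inside the image.
#' @param settings an [extraction_settings()].
#' @param lesion_id,condition optional labels stored on the result.
#' @return an object of class `feature_vector`: named numeric vector of
#'   length 104 (catalog order) with attributes `lesion_id`, `condition`,
#'   `settings_id`.
#' @export
extract_features <- function(image, mask, settings = extraction_settings(),
                             lesion_id = NA, condition = NA_character_) {
  img <- pixels_of(image)
  mask <- as_mask(mask)
  stopifnot_same_shape(img, mask)
  if (sum(mask) < 9)
    stop("mask too small: radiomic matrices need at least 9 pixels",
         call. = FALSE)
  if (inherits(image, "phantom_image") && is.na(condition))
    condition <- image$meta$condition

  fo <- firstorder_features(img, mask, settings)
  lv <- crop_levels(img, mask, settings)
  vals <- c(fo,
            glcm_features(lv, settings),
            gldm_features(lv, settings),
            glrlm_features(lv, settings),
            glszm_features(lv, settings),
            ngtdm_features(lv, settings),
            IQwavelet_global = iq_wavelet(img, scope = "global"),
            IQwavelet_local = iq_wavelet(img, mask, scope = "local"))
  catalog <- build_catalog()
  vals <- vals[catalog$feature]
  stopifnot(!anyNA(names(vals)))
  structure(vals, class = "feature_vector", lesion_id = lesion_id,
            condition = condition, settings_id = settings$id)
}

#' Extract features for every test lesion under every condition
#'
#' Applies the VOI-reuse rule: masks defined on the reference images are
#' applied unchanged to the fast and restored images.
#'
#' @param images named list of image lists, one per condition, e.g.
#'   `list(reference = ..., fast = ..., dl = ...)`; each element is a list of
#'   `phantom_image`s in the same order, and masks are taken from the
#'   reference images.
#' @param settings an [extraction_settings()].
#' @return a long-format data.frame (`lesion`, `condition`, `feature`,
#'   `value`) of class `paired_feature_table`, complete for every catalog
#'   feature and condition.
#' @export
extract_feature_table <- function(images, settings = extraction_settings()) {
  stopifnot(is.list(images), !is.null(names(images)))
  ref <- images[[1]]
  rows <- list()
  lesion_counter <- 0L
  for (i in seq_along(ref)) {
    masks <- ref[[i]]$lesion_masks
    for (k in seq_along(masks)) {
      lesion_counter <- lesion_counter + 1L
      for (cond in names(images)) {
        fv <- extract_features(images[[cond]][[i]], masks[[k]], settings,
                               lesion_id = lesion_counter, condition = cond)
        rows[[length(rows) + 1]] <- data.frame(
          lesion = lesion_counter, condition = cond,
          feature = names(fv), value = as.numeric(fv),
          row.names = NULL)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("paired_feature_table", "data.frame")
  out
}
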