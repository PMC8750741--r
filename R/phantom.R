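#' Configuration for the synthetic brain-slice phantom
#'
#' Defines a seeded 2D phantom emulating a post-gadolinium T1-weighted brain
#' slice: an elliptical head with a bright rim, smooth parenchymal texture,
#' darker ventricle-like inclusions, and one or more hyperintense
#' quasi-elliptical lesions standing in for contrast-enhancing brain
#' metastases. Every downstream stage (degradation, restoration, radiomics,
#' stability statistics) can be exercised on these phantoms without any
#' external data.
#'
#' @param matrix_size positive even integer, pixels per side (default 256).
#' @param n_lesions non-negative integer, number of hyperintense lesions.
#' @param lesion_radius_range numeric length-2, lesion radius interval in
#'   pixels; all radii must be >= 2 so masks have at least ~12 pixels.
#' @param lesion_contrast ratio (> 1) of lesion-mask mean intensity to the
#'   parenchyma mean, imposed exactly before noise.
#' @param background_texture_scale correlation length, in pixels, of the
#'   smooth parenchymal texture (Gaussian-filtered white noise).
#' @param psf_sigma acquisition point-spread surrogate: s.d. in pixels of a
#'   Gaussian blur applied to the noise-free anatomy so slices are
#'   band-limited the way reconstructed magnitude-MR images are; without it
#'   the phantom would carry unphysical pixel-scale edges and its
#'   finest-scale wavelet content would be structure rather than noise.
#'   Set 0 to disable.
#' @param baseline_noise_sigma image-domain noise s.d. in intensity units,
#'   added to the reference in the Rician (magnitude-MRI) family so that
#'   references share the noise family of clinical NEX=2 images.
#' @param intensity_max maximum expected pixel value; the PSNR peak value
#'   (MAXI) surrogate. Lesion peaks may slightly exceed it; it is a scale,
#'   not a hard clip.
#' @param seed integer RNG seed; together with the other fields it fully
#'   determines every pixel and mask.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(matrix_size = 256L,
                           n_lesions = 2L,
                           lesion_radius_range = c(3, 8),
                           lesion_contrast = 1.8,
                           background_texture_scale = 4,
                           psf_sigma = 0.8,
                           baseline_noise_sigma = 0,
                           intensity_max = 255,
                           seed = 1L) {
  matrix_size <- as.integer(matrix_size)
  if (matrix_size <= 0 || matrix_size %% 2L != 0L)
    stop("matrix_size must be a positive even integer", call. = FALSE)
  if (n_lesions < 0) stop("n_lesions must be non-negative", call. = FALSE)
  if (length(lesion_radius_range) != 2 || any(lesion_radius_range < 2))
    stop("lesion_radius_range must be an interval with all radii >= 2 pixels",
         call. = FALSE)
  if (lesion_contrast <= 1) stop("lesion_contrast must be > 1", call. = FALSE)
  if (baseline_noise_sigma < 0)
    stop("baseline_noise_sigma must be >= 0", call. = FALSE)
  if (psf_sigma < 0) stop("psf_sigma must be >= 0", call. = FALSE)
  if (intensity_max <= 0) stop("intensity_max must be > 0", call. = FALSE)
  structure(list(matrix_size = matrix_size,
                 n_lesions = as.integer(n_lesions),
                 lesion_radius_range = sort(as.numeric(lesion_radius_range)),
                 lesion_contrast = lesion_contrast,
                 background_texture_scale = background_texture_scale,
                 psf_sigma = psf_sigma,
                 baseline_noise_sigma = baseline_noise_sigma,
                 intensity_max = intensity_max,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

new_phantom_image <- function(pixels, lesion_masks, meta) {
  structure(list(pixels = pixels, lesion_masks = lesion_masks, meta = meta),
            class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("<phantom_image %dx%d, %d lesion mask(s), condition '%s'>\n",
              nrow(x$pixels), ncol(x$pixels), length(x$lesion_masks),
              x$meta$condition))
  invisible(x)
}

# pixel-centre coordinate grids
coord_grids <- function(n) {
  ax <- seq_len(n) - 0.5
  list(I = matrix(ax, n, n), J = matrix(ax, n, n, byrow = TRUE))
}

#' Generate one synthetic brain slice with lesion masks
#'
#' Deterministic for a fixed configuration: the same `phantom_config` yields
#' bit-identical pixels and masks on every call. The lesion-mask mean
#' intensity is calibrated exactly to `lesion_contrast` times the parenchyma
#' mean before any noise is added.
#'
#' @param config a [phantom_config()].
#' @return a `phantom_image`: `pixels` (matrix, all finite and >= 0),
#'   `lesion_masks` (list of logical matrices, each a connected region inside
#'   the head), and `meta` (seed, config id, condition label `"reference"`,
#'   head/parenchyma masks, intensity_max).
#' @export
generate_slice <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, generate_slice_impl(config))
}

generate_slice_impl <- function(config) {
  n <- config$matrix_size
  imax <- config$intensity_max
  g <- coord_grids(n)
  cx <- n / 2 + runif(1, -0.02, 0.02) * n
  cy <- n / 2 + runif(1, -0.02, 0.02) * n
  ax <- n * runif(1, 0.34, 0.42)   # head semi-axes: area fraction 0.41-0.61
  ay <- n * runif(1, 0.38, 0.46)
  r2 <- ((g$I - cx) / ax)^2 + ((g$J - cy) / ay)^2
  head <- r2 <= 1
  rim <- r2 <= 1 & r2 > 0.90^2
  interior <- r2 <= 0.90^2

  pixels <- matrix(0, n, n)
  pixels[head] <- 0.42 * imax
  pixels[rim] <- 0.85 * imax

  # smooth parenchymal texture: Gaussian-filtered white noise rescaled to a
  # fixed s.d., giving non-trivial co-occurrence/run-length/zone structure
  tex <- gauss_blur_periodic(matrix(rnorm(n * n), n, n),
                             config$background_texture_scale)
  tex <- tex / max(sd(tex), .Machine$double.eps) * 0.06 * imax
  pixels[interior] <- pixels[interior] + tex[interior]

  # ventricle-like darker inclusions near the centre
  vent <- matrix(FALSE, n, n)
  for (s in c(-1, 1)) {
    vc <- c(cx + s * 0.08 * n * runif(1, 0.8, 1.2),
            cy - 0.03 * n * runif(1, 0.5, 1.5))
    va <- 0.045 * n * runif(1, 0.8, 1.2)
    vb <- 0.10 * n * runif(1, 0.8, 1.2)
    vent <- vent | (((g$I - vc[1]) / va)^2 + ((g$J - vc[2]) / vb)^2 <= 1)
  }
  vent <- vent & interior
  pixels[vent] <- 0.22 * imax + 0.3 * tex[vent]

  # lesions: plateau-profile hyperintense blobs fully inside the head
  masks <- list()
  profiles <- list()
  supports <- list()
  occupied <- vent
  placeable <- interior & !vent
  for (k in seq_len(config$n_lesions)) {
    placed <- FALSE
    for (try in seq_len(400L)) {
      r <- runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2])
      li <- cx + runif(1, -1, 1) * 0.75 * ax
      lj <- cy + runif(1, -1, 1) * 0.75 * ay
      # elongate slightly so lesions are quasi-elliptical, random orientation
      ecc <- runif(1, 1, 1.4); th <- runif(1, 0, pi)
      u <- (g$I - li) * cos(th) + (g$J - lj) * sin(th)
      v <- -(g$I - li) * sin(th) + (g$J - lj) * cos(th)
      d2 <- (u / (r * ecc))^2 + (v / r)^2
      mask <- d2 <= 1
      if (!any(mask)) next
      ok_inside <- all(placeable[mask]) && sum(mask) >= 9
      ok_apart <- !any(occupied[mask])
      if (ok_inside && ok_apart) {
        # plateau profile: solidly enhancing interior with a smooth sigmoid
        # rolloff centred OUTSIDE the mask edge (u = sqrt(d2) = 1), so the
        # masked interior stays flat and its fine-scale content is texture
        # and noise, not border gradient — the regime of full-resolution
        # enhancing lesions
        u <- sqrt(d2)
        profiles[[k]] <- 1 / (1 + exp((u - 1.35) / 0.1)) * (d2 <= 4)
        masks[[k]] <- mask
        supports[[k]] <- d2 <= 4      # profile tail + blur spill zone
        occupied <- occupied | supports[[k]]
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("lesion %d could not be placed inside the head region", k),
           call. = FALSE)
  }

  # band-limit the noise-free anatomy (acquisition point-spread surrogate);
  # blur base and profiles separately so the contrast calibration below
  # stays exact under the linear blur
  if (config$psf_sigma > 0) {
    pixels <- gauss_blur_periodic(pixels, config$psf_sigma)
    profiles <- lapply(profiles, gauss_blur_periodic, config$psf_sigma)
  }

  # calibrate lesion contrast exactly: mean over mask becomes
  # lesion_contrast * parenchyma mean (parenchyma = interior minus rim,
  # ventricles and the whole lesion support zones, so profile tails never
  # contaminate the reference region)
  lesion_any <- Reduce(`|`, supports, matrix(FALSE, n, n))
  parenchyma <- interior & !vent & !lesion_any
  m_par <- mean(pixels[parenchyma])
  for (k in seq_along(masks)) {
    m0 <- mean(pixels[masks[[k]]])
    target <- config$lesion_contrast * m_par
    s <- (target - m0) / mean(profiles[[k]][masks[[k]]])
    pixels <- pixels + s * profiles[[k]]
  }

  pixels[pixels < 0] <- 0

  meta <- list(seed = config$seed,
               config_id = config_id(unclass(config)),
               condition = "reference",
               intensity_max = imax,
               head_mask = head,
               parenchyma_mask = parenchyma)
  img <- new_phantom_image(pixels, masks, meta)

  # references share the magnitude-MRI noise family: small Rician noise via
  # the k-space route used by the degradation module
  if (config$baseline_noise_sigma > 0) {
    img$pixels <- rician_noisify(img$pixels, config$baseline_noise_sigma,
                                 seed = config$seed + 104729L)
  }
  img
}

#' Generate a seeded phantom cohort with a train/validation/test partition
#'
#' Each image is an independent phantom drawn from `config` with a per-image
#' seed derived from `config$seed`. The partition is by image, disjoint and
#' exhaustive; sizes follow the rounding rule recorded in the manifest
#' (train rounded to nearest, validation floored, test takes the remainder).
#'
#' @param config a [phantom_config()]; its `seed` acts as the master seed.
#' @param n_images number of images (>= 10).
#' @param n_test_lesions minimum number of lesion masks required across the
#'   test partition (the stability statistics need enough lesions).
#' @param fractions train/validation/test fractions (default c(0.68, 0.17,
#'   0.15), mirroring a 9756/2438/2049-style split).
#' @return a list of class `phantom_cohort`: `images` (list of
#'   `phantom_image`), `partition` (factor train/val/test per image) and
#'   `manifest` (seeds, fractions, rounding rule, config id).
#' @export
generate_cohort <- function(config, n_images, n_test_lesions,
                            fractions = c(train = 0.68, val = 0.17, test = 0.15)) {
  stopifnot(inherits(config, "phantom_config"))
  n_images <- as.integer(n_images)
  if (n_images < 10) stop("n_images must be >= 10", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("partition fractions must sum to 1", call. = FALSE)

  n_train <- round(fractions[[1]] * n_images)
  n_val <- floor(fractions[[2]] * n_images)
  n_test <- n_images - n_train - n_val
  if (n_test < 1 || n_train < 1 || n_val < 1)
    stop("partition fractions leave an empty partition", call. = FALSE)

  max_lesions_test <- n_test * config$n_lesions
  if (max_lesions_test < n_test_lesions)
    stop(sprintf(paste0("configuration cannot reach %d test lesions: test ",
                        "partition has %d images x %d lesions"),
                 n_test_lesions, n_test, config$n_lesions), call. = FALSE)

  seeds <- config$seed + seq_len(n_images) * 1000L
  images <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    ci <- config
    ci$seed <- seeds[i]
    images[[i]] <- generate_slice(ci)
    images[[i]]$meta$image_id <- i
  }
  partition <- factor(rep(c("train", "val", "test"), c(n_train, n_val, n_test)),
                      levels = c("train", "val", "test"))
  manifest <- list(master_seed = config$seed,
                   image_seeds = seeds,
                   n_images = n_images,
                   fractions = as.list(fractions),
                   rounding_rule = paste("n_train = round(f_train*n);",
                                         "n_val = floor(f_val*n);",
                                         "n_test = remainder"),
                   partition_sizes = list(train = n_train, val = n_val,
                                          test = n_test),
                   config_id = config_id(unclass(config)))
  structure(list(images = images, partition = partition, manifest = manifest),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  sz <- x$manifest$partition_sizes
  cat(sprintf("<phantom_cohort: %d images (train %d / val %d / test %d)>\n",
              x$manifest$n_images, sz$train, sz$val, sz$test))
  invisible(x)
}

cohort_subset <- function(cohort, part) {
  cohort$images[cohort$partition == part]
}
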