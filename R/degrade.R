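#' Fast-acquisition degradation configuration
#'
#' Two simulated time-saving acquisitions: `"resolution"` halves the
#' acquisition matrix (downsample by `factor` with linear interpolation,
#' upsample back, so input and output sizes match), and `"nex"` halves the
#' number of excitations (additive complex Gaussian noise in k-space,
#' yielding Rician magnitude noise in the image).
#'
#' @param mode `"resolution"`, `"nex"`, or `"none"` (identity passthrough,
#'   used by the identity-pipeline checks).
#' @param factor integer >= 2, resolution mode; must divide the image side.
#' @param kspace_sigma non-negative, NEX mode; noise s.d. as a fraction of
#'   the k-space amplitude scale. Under the unitary FFT convention used here
#'   that scale is the DC bin divided by sqrt(m*n), i.e. the image mean, so
#'   the implied image-domain noise s.d. is `kspace_sigma * mean(image)`
#'   independent of matrix size (unit fallback scale for an all-zero image).
#'   The default 0.08 places reference-vs-fast PSNR of default phantoms in
#'   the low-30s dB.
#' @param seed integer seed for the NEX noise draw.
#' @return an object of class `degradation_config`.
#' @export
degradation_config <- function(mode = c("resolution", "nex", "none"),
                               factor = 2L, kspace_sigma = 0.08, seed = 1L) {
  mode <- match.arg(mode)
  factor <- as.integer(factor)
  if (mode == "resolution" && factor < 2)
    stop("factor must be an integer >= 2", call. = FALSE)
  if (kspace_sigma < 0) stop("kspace_sigma must be >= 0", call. = FALSE)
  structure(list(mode = mode, factor = factor, kspace_sigma = kspace_sigma,
                 seed = as.integer(seed)),
            class = "degradation_config")
}

pixels_of <- function(image) if (inherits(image, "phantom_image")) image$pixels else image

# rebuild an output object of the same kind as the input, with the fast
# condition label and masks/metadata untouched
rewrap_degraded <- function(image, pixels, label = "fast") {
  if (inherits(image, "phantom_image")) {
    out <- image
    out$pixels <- pixels
    out$meta$condition <- label
    out
  } else {
    pixels
  }
}

#' Simulate acquisition-matrix reduction (resolution degradation)
#'
#' Downsamples by `factor` with linear interpolation and linearly upsamples
#' back to the original grid, so the output has the same pixel dimensions as
#' the input (a 256x256 image passes through a 128x128 acquisition for
#' `factor = 2`). Detail at or above the Nyquist frequency of the reduced
#' matrix is destroyed; total image variance never increases. Masks and
#' metadata are carried through unchanged; the condition label becomes
#' `"fast"`.
#'
#' @param image a `phantom_image` or plain numeric matrix.
#' @param factor integer >= 2 dividing both image sides.
#' @return degraded image of the same type and size as the input.
#' @export
degrade_resolution <- function(image, factor = 2L) {
  x <- pixels_of(image)
  factor <- as.integer(factor)
  h <- nrow(x); w <- ncol(x)
  if (h %% factor != 0 || w %% factor != 0)
    stop(sprintf("image side lengths (%dx%d) are not divisible by factor %d",
                 h, w, factor), call. = FALSE)
  low <- resize_bilinear(x, h %/% factor, w %/% factor)
  up <- resize_bilinear(low, h, w)
  rewrap_degraded(image, up)
}

# Add magnitude-domain Rician noise with an absolute image-domain sigma:
# DFT -> i.i.d. N(0, sigma) on real and imaginary parts -> inverse DFT ->
# pixel-wise magnitude. Under the unitary convention the image-domain and
# k-space sigmas coincide.
rician_noisify <- function(pixels, sigma_abs, seed) {
  if (sigma_abs <= 0) return(abs(pixels))
  with_seed(seed, {
    k <- fft2_unitary(pixels)
    noise <- complex(real = rnorm(length(k), 0, sigma_abs),
                     imaginary = rnorm(length(k), 0, sigma_abs))
    Mod(ifft2_unitary(k + noise))
  })
}

#' Simulate NEX halving (k-space noise degradation)
#'
#' Transforms the image to the Fourier domain, adds i.i.d. zero-mean
#' Gaussian noise independently to the real and imaginary parts, transforms
#' back, and takes the pixel-wise magnitude. The resulting image-domain noise
#' is Rician (Rayleigh where the signal is zero). Deterministic given `seed`;
#' masks and metadata are untouched and the condition label becomes `"fast"`.
#'
#' @param image a `phantom_image` or numeric matrix.
#' @param kspace_sigma noise s.d. as a fraction of the k-space amplitude
#'   scale (see [degradation_config()]); must be >= 0.
#' @param seed integer seed.
#' @return degraded image of the same type and size as the input.
#' @export
degrade_nex <- function(image, kspace_sigma = 0.08, seed = 1L) {
  if (kspace_sigma < 0) stop("kspace_sigma must be >= 0", call. = FALSE)
  x <- pixels_of(image)
  if (kspace_sigma == 0) return(rewrap_degraded(image, abs(x)))
  scale <- mean(x)
  if (scale <= 0) scale <- 1          # unit fallback for signal-free images
  out <- rician_noisify(x, kspace_sigma * scale, seed)
  rewrap_degraded(image, out)
}

#' Apply a degradation configuration to an image
#'
#' @param image a `phantom_image` or numeric matrix.
#' @param config a [degradation_config()].
#' @param seed optional seed overriding `config$seed` (used to decorrelate
#'   noise draws across a cohort).
#' @return degraded image; mode `"none"` returns the input with the `"fast"`
#'   label (identity passthrough).
#' @export
degrade <- function(image, config, seed = NULL) {
  stopifnot(inherits(config, "degradation_config"))
  switch(config$mode,
         resolution = degrade_resolution(image, config$factor),
         nex = degrade_nex(image, config$kspace_sigma,
                           if (is.null(seed)) config$seed else seed),
         none = rewrap_degraded(image, pixels_of(image)))
}
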