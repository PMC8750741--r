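#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_value^2 / MSE)` in dB. `max_value` is the maximum
#' *possible* pixel value of the image (taken from configuration, e.g. the
#' phantom `intensity_max`), not the observed maximum. Identical images have
#' zero MSE; the documented sentinel `Inf` is returned.
#'
#' @param reference,test numeric matrices of identical shape.
#' @param max_value positive scalar peak value (MAXI).
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(reference, test, max_value) {
  reference <- pixels_of(reference); test <- pixels_of(test)
  stopifnot_same_shape(reference, test)
  if (max_value <= 0) stop("max_value must be > 0", call. = FALSE)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

sobel_kx <- function() matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
sobel_ky <- function() t(sobel_kx())

#' Sobel gradient-magnitude map
#'
#' Correlates the image with the two 3x3 Sobel kernels and returns the
#' per-pixel magnitude `sqrt(Gx^2 + Gy^2)`. The border policy is replicate
#' padding, so the output has the same size as the input; interior pixels
#' are unaffected by the policy.
#'
#' @param image numeric matrix, at least 3x3.
#' @return non-negative matrix of the same size.
#' @export
sobel_gradient_magnitude <- function(image) {
  image <- pixels_of(image)
  if (nrow(image) < 3 || ncol(image) < 3)
    stop("image must be at least 3x3", call. = FALSE)
  p <- pad_replicate(image, 1L)
  gx <- corr2_valid(p, sobel_kx())
  gy <- corr2_valid(p, sobel_ky())
  sqrt(gx^2 + gy^2)
}

# Gaussian SSIM window, normalised to sum 1.
ssim_window <- function(size = 11L, sigma = 1.5) {
  ax <- seq_len(size) - (size + 1) / 2
  k <- exp(-ax^2 / (2 * sigma^2))
  w <- outer(k, k)
  w / sum(w)
}

# Windowed SSIM statistics at one scale: luminance and contrast-structure
# maps over valid window positions.
ssim_maps <- function(x, y, max_value, window = 11L, sigma = 1.5) {
  if (min(dim(x)) < window)
    stop("image smaller than the SSIM window", call. = FALSE)
  c1 <- (0.01 * max_value)^2
  c2 <- (0.03 * max_value)^2
  w <- ssim_window(window, sigma)
  mu_x <- corr2_valid(x, w); mu_y <- corr2_valid(y, w)
  x2 <- corr2_valid(x * x, w); y2 <- corr2_valid(y * y, w)
  xy <- corr2_valid(x * y, w)
  sx2 <- x2 - mu_x^2; sy2 <- y2 - mu_y^2; sxy <- xy - mu_x * mu_y
  a1 <- 2 * mu_x * mu_y + c1; b1 <- mu_x^2 + mu_y^2 + c1
  a2 <- 2 * sxy + c2; b2 <- sx2 + sy2 + c2
  list(l = a1 / b1, cs = a2 / b2,
       mu_x = mu_x, mu_y = mu_y, sxy = sxy,
       a1 = a1, b1 = b1, a2 = a2, b2 = b2, w = w)
}

#' Structural similarity index (single scale)
#'
#' Mean of the canonical SSIM map (covariance form, Gaussian 11x11 window,
#' sigma 1.5, valid positions only) with constants `c1 = (0.01 L)^2`,
#' `c2 = (0.03 L)^2` for dynamic range `L = max_value`.
#'
#' @param reference,test numeric matrices of identical shape.
#' @param max_value dynamic range of the images.
#' @param window,sigma Gaussian window size and width.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(reference, test, max_value, window = 11L, sigma = 1.5) {
  reference <- pixels_of(reference); test <- pixels_of(test)
  stopifnot_same_shape(reference, test)
  m <- ssim_maps(reference, test, max_value, window, sigma)
  mean(m$l * m$cs)
}

#' Percent difference map over a region of interest
#'
#' `abs(post - reference) / reference * 100` over the mask. Pixels whose
#' reference value is below `1e-6 * max_value` are excluded from the map and
#' counted, since the formula divides by the reference.
#'
#' @param post,reference numeric matrices of identical shape.
#' @param mask logical matrix; the region of interest.
#' @param max_value peak value used to scale the exclusion epsilon.
#' @return list: `map` (percent values, `NA` outside the mask and at excluded
#'   pixels), `mean`, `sd` (over included pixels), `n`, `n_excluded`.
#' @export
difference_map <- function(post, reference, mask, max_value) {
  post <- pixels_of(post); reference <- pixels_of(reference)
  stopifnot_same_shape(post, reference)
  mask <- as_mask(mask)
  stopifnot_same_shape(reference, mask)
  eps <- 1e-6 * max_value
  ok <- mask & reference >= eps
  n_excluded <- sum(mask) - sum(ok)
  if (!any(ok)) stop("empty ROI after excluding near-zero reference pixels",
                     call. = FALSE)
  map <- matrix(NA_real_, nrow(post), ncol(post))
  map[ok] <- abs(post[ok] - reference[ok]) / reference[ok] * 100
  v <- map[ok]
  list(map = map, mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
       n = length(v), n_excluded = n_excluded)
}

#' Coefficient of variation and entropy within a region of interest
#'
#' Both reflect noise in the image. CV is returned as the ratio sd/mean
#' (render as percent in reports as needed). Entropy is the Shannon entropy,
#' in bits, of the ROI intensity histogram discretized with the same fixed
#' bin width used by the radiomic first-order entropy.
#'
#' @param image numeric matrix or `phantom_image`.
#' @param mask logical matrix, non-empty.
#' @param bin_width intensity bin width for the entropy histogram.
#' @return list with `cv` (ratio) and `entropy` (bits).
#' @export
roi_stats <- function(image, mask, bin_width = 25) {
  image <- pixels_of(image)
  mask <- as_mask(mask)
  stopifnot_same_shape(image, mask)
  v <- image[mask]
  if (length(v) == 0) stop("mask is empty", call. = FALSE)
  m <- mean(v)
  if (m == 0) stop("CV undefined: ROI mean is zero", call. = FALSE)
  s <- sqrt(mean((v - m)^2))
  lv <- discretize_fbw(v, bin_width)
  p <- tabulate(lv) / length(lv)
  p <- p[p > 0]
  list(cv = s / m, entropy = -sum(p * log2(p)))
}
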