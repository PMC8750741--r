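#' Weights of the mixed restoration loss
#'
#' The training loss is `MSE + w_mge * MGE + w_ssim * (1 - MS-SSIM)`, where
#' MGE is the mean squared difference between the Sobel gradient-magnitude
#' maps of reference and prediction. The structural term enters as a
#' dissimilarity `1 - MS-SSIM`, the only form under which a perfect
#' prediction minimises every component. Defaults put weight 0.1 on both
#' auxiliary terms.
#'
#' @param w_mge,w_ssim non-negative weights.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(w_mge = 0.1, w_ssim = 0.1) {
  if (w_mge < 0 || w_ssim < 0) stop("loss weights must be >= 0", call. = FALSE)
  structure(list(w_mge = w_mge, w_ssim = w_ssim), class = "loss_weights")
}

#' Mixed restoration loss and its components
#'
#' @param reference,prediction numeric matrices of identical shape with
#'   finite values.
#' @param weights a [loss_weights()].
#' @param max_value dynamic range used by the SSIM constants (training
#'   operates on images normalised to `[0, 1]`, so the default is 1).
#' @return a `loss_value` list: `total`, `mse`, `mge`, `ms_ssim_term`
#'   (the dissimilarity `1 - MS-SSIM`), with
#'   `total = mse + w_mge * mge + w_ssim * ms_ssim_term` exactly.
#' @export
mix_loss <- function(reference, prediction, weights = loss_weights(),
                     max_value = 1) {
  reference <- pixels_of(reference); prediction <- pixels_of(prediction)
  stopifnot_same_shape(reference, prediction)
  if (!all(is.finite(reference)) || !all(is.finite(prediction)))
    stop("images must be finite", call. = FALSE)
  mse <- mean((prediction - reference)^2)
  mge <- mean((sobel_gradient_magnitude(prediction) -
                 sobel_gradient_magnitude(reference))^2)
  ms_term <- 1 - ms_ssim(reference, prediction, max_value)
  structure(list(total = mse + weights$w_mge * mge + weights$w_ssim * ms_term,
                 mse = mse, mge = mge, ms_ssim_term = ms_term),
            class = "loss_value")
}

# adjoint of sobel filtering (replicate pad then valid correlation)
sobel_adjoint <- function(g, k) pad_replicate_adj(corr2_full_adj(g, k), 1L)

# Mixed loss with analytic gradient with respect to the prediction; the
# training loop's workhorse. Components match mix_loss() exactly.
mix_loss_grad <- function(reference, prediction, weights = loss_weights(),
                          max_value = 1) {
  n <- length(reference)
  diff <- prediction - reference
  mse <- mean(diff^2)
  g_mse <- 2 * diff / n

  kx <- sobel_kx(); ky <- sobel_ky()
  pr <- pad_replicate(prediction, 1L)
  gx_p <- corr2_valid(pr, kx); gy_p <- corr2_valid(pr, ky)
  gp <- sqrt(gx_p^2 + gy_p^2)
  gr <- sobel_gradient_magnitude(reference)
  dg <- gp - gr
  mge <- mean(dg^2)
  denom <- pmax(gp, 1e-12)
  d <- 2 * dg / n
  g_mge <- sobel_adjoint(d * gx_p / denom, kx) +
    sobel_adjoint(d * gy_p / denom, ky)

  ms <- ms_ssim_value_grad(reference, prediction, max_value)
  ms_term <- 1 - ms$value
  g_ms <- -ms$grad

  total <- mse + weights$w_mge * mge + weights$w_ssim * ms_term
  grad <- g_mse + weights$w_mge * g_mge + weights$w_ssim * g_ms
  list(value = structure(list(total = total, mse = mse, mge = mge,
                              ms_ssim_term = ms_term), class = "loss_value"),
       grad = grad)
}
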