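ms_ssim_weights <- function() c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)

# number of scales usable for a given image size and window
ms_ssim_n_scales <- function(dims, window, max_scales = 5L) {
  s <- 0L
  size <- min(dims)
  while (s < max_scales && size >= window) {
    s <- s + 1L
    size <- size %/% 2L
  }
  s
}

#' Multi-scale structural similarity
#'
#' Canonical multi-scale SSIM: contrast-structure terms are computed on
#' Gaussian-windowed patches at successively half-resolution scales (2x2
#' average pooling between scales), the luminance term at the coarsest scale
#' only, and the per-scale means are combined with the published exponents
#' (0.0448, 0.2856, 0.3001, 0.2363, 0.1333). When the image is too small for
#' five scales the scale count is reduced and the exponents renormalised to
#' sum to one. Per-scale means are clamped at a small positive floor before
#' exponentiation, so pathological anticorrelated inputs yield a value near
#' zero rather than a complex power.
#'
#' @param reference,prediction numeric matrices of identical shape, at least
#'   one SSIM window in size.
#' @param max_value dynamic range of the images.
#' @param window,sigma Gaussian window size and width.
#' @param max_scales upper bound on the number of scales (default 5).
#' @return MS-SSIM value in `[-1, 1]` (in practice `[0, 1]` after clamping).
#' @export
ms_ssim <- function(reference, prediction, max_value = 1, window = 11L,
                    sigma = 1.5, max_scales = 5L) {
  reference <- pixels_of(reference); prediction <- pixels_of(prediction)
  stopifnot_same_shape(reference, prediction)
  ms_ssim_value_grad(reference, prediction, max_value, window, sigma,
                     max_scales, want_grad = FALSE)$value
}

# Shared forward/backward for MS-SSIM. The gradient (with respect to the
# prediction) is propagated analytically through the windowed statistics and
# the average-pooling pyramid; used by the training loss.
ms_ssim_value_grad <- function(x, y, max_value, window = 11L, sigma = 1.5,
                               max_scales = 5L, want_grad = TRUE) {
  M <- ms_ssim_n_scales(dim(x), window, max_scales)
  if (M < 1L) stop("image smaller than one SSIM window", call. = FALSE)
  wts <- ms_ssim_weights()[seq_len(M)]
  wts <- wts / sum(wts)
  eps <- 1e-8

  xs <- vector("list", M); ys <- vector("list", M)
  xs[[1]] <- x; ys[[1]] <- y
  for (s in seq_len(M - 1L)) {
    xs[[s + 1]] <- avgpool2_mat(trim_even(xs[[s]]))
    ys[[s + 1]] <- avgpool2_mat(trim_even(ys[[s]]))
  }

  maps <- vector("list", M)
  mcs <- numeric(M); ml <- NA_real_
  for (s in seq_len(M)) {
    maps[[s]] <- ssim_maps(xs[[s]], ys[[s]], max_value, window, sigma)
    mcs[s] <- mean(maps[[s]]$cs)
  }
  ml <- mean(maps[[M]]$l)

  # value = l_M^{w_M} * prod_s cs_s^{w_s}, clamped means
  mcs_c <- pmax(mcs, eps)
  ml_c <- max(ml, eps)
  value <- exp(sum(wts * log(mcs_c)) + wts[M] * log(ml_c))

  if (!want_grad) return(list(value = value))

  # d value / d mcs_s and d value / d ml (zero where clamped)
  dv_dmcs <- ifelse(mcs > eps, value * wts / mcs_c, 0)
  dv_dml <- if (ml > eps) value * wts[M] / ml_c else 0

  g <- NULL
  for (s in rev(seq_len(M))) {
    m <- maps[[s]]
    npix <- length(m$cs)
    gcs <- matrix(dv_dmcs[s] / npix, nrow(m$cs), ncol(m$cs))
    # partials of cs = a2/b2 with respect to the filtered maps
    g_mu_y <- gcs * (-2 * m$mu_x / m$b2 + 2 * m$mu_y * m$a2 / m$b2^2)
    g_y2 <- gcs * (-m$a2 / m$b2^2)
    g_xy <- gcs * (2 / m$b2)
    if (s == M) {
      gl <- matrix(dv_dml / npix, nrow(m$l), ncol(m$l))
      g_mu_y <- g_mu_y + gl * (2 * m$mu_x / m$b1 - 2 * m$mu_y * m$a1 / m$b1^2)
    }
    gs <- corr2_full_adj(g_mu_y, m$w) +
      2 * ys[[s]] * corr2_full_adj(g_y2, m$w) +
      xs[[s]] * corr2_full_adj(g_xy, m$w)
    if (is.null(g)) {
      g <- gs
    } else {
      g <- untrim_even(avgpool2_mat_adj(g), dim(ys[[s]])) + gs
    }
  }
  list(value = value, grad = g)
}

# drop a trailing row/column when a dimension is odd so 2x2 pooling applies
trim_even <- function(x) {
  h <- nrow(x) - nrow(x) %% 2L
  w <- ncol(x) - ncol(x) %% 2L
  x[seq_len(h), seq_len(w), drop = FALSE]
}

# adjoint of trim_even: embed the gradient back into the full-size matrix
untrim_even <- function(g, dims) {
  if (all(dim(g) == dims)) return(g)
  out <- matrix(0, dims[1], dims[2])
  out[seq_len(nrow(g)), seq_len(ncol(g))] <- g
  out
}
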