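# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Unitary 2D discrete Fourier transform and its inverse: with this
# convention i.i.d. Gaussian noise of s.d. sigma in k-space maps to i.i.d.
# Gaussian noise of the same sigma in the image domain.
fft2_unitary <- function(x) fft(x) / sqrt(length(x))
ifft2_unitary <- function(X) fft(X, inverse = TRUE) / sqrt(length(X))

# Periodic Gaussian blur (FFT-based); sigma in pixels.
gauss_blur_periodic <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- nrow(x); m <- ncol(x)
  fi <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fj <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / m
  gi <- exp(-2 * pi^2 * sigma^2 * fi^2)
  gj <- exp(-2 * pi^2 * sigma^2 * fj^2)
  Re(fft(fft(x) * outer(gi, gj), inverse = TRUE)) / length(x)
}

# Bilinear resize with pixel-centre alignment; clamped source coordinates so
# a constant image stays exactly constant.
resize_bilinear <- function(x, new_h, new_w) {
  h <- nrow(x); w <- ncol(x)
  src_i <- pmin(pmax((seq_len(new_h) - 0.5) * h / new_h - 0.5, 0), h - 1)
  src_j <- pmin(pmax((seq_len(new_w) - 0.5) * w / new_w - 0.5, 0), w - 1)
  i0 <- floor(src_i); fi <- src_i - i0
  j0 <- floor(src_j); fj <- src_j - j0
  i1 <- pmin(i0 + 1, h - 1); j1 <- pmin(j0 + 1, w - 1)
  # interpolate rows, then columns
  a <- x[i0 + 1, , drop = FALSE] * (1 - fi) + x[i1 + 1, , drop = FALSE] * fi
  t(t(a[, j0 + 1, drop = FALSE]) * (1 - fj) + t(a[, j1 + 1, drop = FALSE]) * fj)
}

# Readable content identifier for configuration lists (used as a settings
# "hash" in manifests; a canonical key=value string, not cryptographic).
config_id <- function(x) {
  flat <- unlist(x, use.names = TRUE)
  paste(names(flat), vapply(flat, format, character(1), digits = 12),
        sep = "=", collapse = ";")
}

is_binary_mask <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

as_mask <- function(m) {
  if (is.logical(m)) m else matrix(as.logical(m), nrow(m), ncol(m))
}

stopifnot_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("images must have identical dimensions (",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")", call. = FALSE)
}
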