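#' U-Net architecture specification
#'
#' A batch-normalisation-free encoder-decoder with concatenation skip
#' connections: at each of `depth` levels two 3x3 convolution + ReLU blocks
#' followed by 2x2 max pooling; a two-convolution bottleneck; and a mirrored
#' decoder using nearest-neighbour upsampling, a channel-halving
#' convolution, concatenation with the encoder skip, and two further
#' convolution + ReLU blocks; a final linear 1x1 convolution maps back to
#' one channel. Batch normalisation is deliberately absent: it degrades
#' restoration accuracy in super-resolution settings.
#'
#' With `residual = TRUE` (default) the network output is added to its
#' input, so the convolutional path learns the degradation *residual*
#' rather than the full image mapping. Restoration starts from an
#' approximate identity and converges in far fewer epochs — essential for
#' CPU-scale training — without changing what the trained model computes.
#'
#' @param depth number of down/up levels (default 4); input sides must be
#'   divisible by `2^depth`.
#' @param base_channels channels at the first level (default 32); level `l`
#'   uses `base_channels * 2^(l-1)`.
#' @param use_batch_norm must be `FALSE`; present so configurations are
#'   explicit about the choice.
#' @param residual add a global input-to-output skip (residual learning).
#' @return an object of class `unet_spec`.
#' @export
unet_spec <- function(depth = 4L, base_channels = 32L, use_batch_norm = FALSE,
                      residual = TRUE) {
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  if (depth < 1 || base_channels < 1)
    stop("depth and base_channels must be positive", call. = FALSE)
  if (isTRUE(use_batch_norm))
    stop("batch normalisation is deliberately not part of this architecture",
         call. = FALSE)
  structure(list(depth = depth, base_channels = base_channels,
                 use_batch_norm = FALSE, skip_mode = "concatenation",
                 residual = isTRUE(residual)),
            class = "unet_spec")
}

conv_layer <- function(k, cin, cout) {
  # He initialisation for ReLU networks
  sd <- sqrt(2 / (k * k * cin))
  list(W = matrix(rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout),
       b = rep(0, cout))
}

#' Initialise U-Net parameters
#'
#' @param spec a [unet_spec()].
#' @param seed integer RNG seed for the weight draw.
#' @param in_channels input channel count (default 1).
#' @return an object of class `unet_model` with untrained weights.
#' @export
unet_init <- function(spec, seed = 1L, in_channels = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  with_seed(seed, {
    d <- spec$depth
    ch <- spec$base_channels * 2^(seq_len(d + 1) - 1)
    enc <- vector("list", d)
    cin <- in_channels
    for (l in seq_len(d)) {
      enc[[l]] <- list(c1 = conv_layer(3L, cin, ch[l]),
                       c2 = conv_layer(3L, ch[l], ch[l]))
      cin <- ch[l]
    }
    bott <- list(c1 = conv_layer(3L, ch[d], ch[d + 1]),
                 c2 = conv_layer(3L, ch[d + 1], ch[d + 1]))
    dec <- vector("list", d)
    for (l in seq_len(d)) {
      above <- if (l == d) ch[d + 1] else ch[l + 1]
      dec[[l]] <- list(up = conv_layer(3L, above, ch[l]),
                       c1 = conv_layer(3L, 2L * ch[l], ch[l]),
                       c2 = conv_layer(3L, ch[l], ch[l]))
    }
    final <- conv_layer(1L, ch[1], 1L)
    structure(list(spec = spec, seed = as.integer(seed),
                   params = list(enc = enc, bott = bott, dec = dec,
                                 final = final)),
              class = "unet_model")
  })
}

#' @export
print.unet_model <- function(x, ...) {
  np <- length(unlist(x$params))
  cat(sprintf("<unet_model depth %d, base %d channels, %d parameters>\n",
              x$spec$depth, x$spec$base_channels, np))
  invisible(x)
}

infer_k <- function(layer, x) as.integer(round(sqrt(nrow(layer$W) / dim(x)[3])))

crelu_fwd <- function(layer, x) {
  k <- infer_k(layer, x)
  pre <- conv2d_fwd(x, layer$W, layer$b, k)
  y <- pre
  y[y < 0] <- 0
  list(y = y, x = x, mask = pre > 0, k = k)
}

crelu_bwd <- function(layer, cache, gy) {
  conv2d_bwd(cache$x, layer$W, gy * cache$mask, cache$k)
}

cube_cat <- function(a, b) {
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

# Forward pass; x is a single-channel matrix. With want_cache the
# intermediate activations needed for backpropagation are retained.
unet_forward <- function(model, x, want_cache = FALSE) {
  d <- model$spec$depth
  if (nrow(x) %% 2^d != 0 || ncol(x) %% 2^d != 0)
    stop(sprintf("input sides (%dx%d) must be divisible by 2^depth = %d",
                 nrow(x), ncol(x), 2^d), call. = FALSE)
  p <- model$params
  h <- array(x, c(nrow(x), ncol(x), 1L))
  cache <- list(enc = vector("list", d), dec = vector("list", d))
  skips <- vector("list", d)
  for (l in seq_len(d)) {
    a <- crelu_fwd(p$enc[[l]]$c1, h)
    b <- crelu_fwd(p$enc[[l]]$c2, a$y)
    skips[[l]] <- b$y
    pl <- maxpool2_fwd(b$y)
    h <- pl$y
    if (want_cache) cache$enc[[l]] <- list(a = a, b = b, idx = pl$idx)
  }
  ba <- crelu_fwd(p$bott$c1, h)
  bb <- crelu_fwd(p$bott$c2, ba$y)
  h <- bb$y
  if (want_cache) cache$bott <- list(a = ba, b = bb)
  for (l in rev(seq_len(d))) {
    up <- upsample2_fwd(h)
    u <- crelu_fwd(p$dec[[l]]$up, up)
    hc <- cube_cat(skips[[l]], u$y)
    a <- crelu_fwd(p$dec[[l]]$c1, hc)
    b <- crelu_fwd(p$dec[[l]]$c2, a$y)
    h <- b$y
    if (want_cache)
      cache$dec[[l]] <- list(u = u, a = a, b = b,
                             n_skip = dim(skips[[l]])[3])
  }
  y <- conv2d_fwd(h, p$final$W, p$final$b, 1L)[, , 1]
  if (isTRUE(model$spec$residual)) y <- y + x
  if (want_cache) cache$final_in <- h
  list(y = y, cache = if (want_cache) cache else NULL)
}

# Backpropagation; gy is the loss gradient with respect to the output
# matrix. Returns gradients in the same nested structure as model$params.
unet_backward <- function(model, cache, gy) {
  d <- model$spec$depth
  p <- model$params
  grads <- list(enc = vector("list", d), bott = NULL,
                dec = vector("list", d), final = NULL)
  g <- array(gy, c(nrow(gy), ncol(gy), 1L))
  rf <- conv2d_bwd(cache$final_in, p$final$W, g, 1L)
  grads$final <- list(W = rf$gW, b = rf$gb)
  g <- rf$gx
  gskip <- vector("list", d)
  for (l in seq_len(d)) {
    cb <- cache$dec[[l]]
    r2 <- crelu_bwd(p$dec[[l]]$c2, cb$b, g)
    r1 <- crelu_bwd(p$dec[[l]]$c1, cb$a, r2$gx)
    ns <- cb$n_skip
    gskip[[l]] <- r1$gx[, , seq_len(ns), drop = FALSE]
    gu <- r1$gx[, , ns + seq_len(dim(r1$gx)[3] - ns), drop = FALSE]
    ru <- crelu_bwd(p$dec[[l]]$up, cb$u, gu)
    grads$dec[[l]] <- list(up = list(W = ru$gW, b = ru$gb),
                           c1 = list(W = r1$gW, b = r1$gb),
                           c2 = list(W = r2$gW, b = r2$gb))
    g <- upsample2_bwd(ru$gx)
  }
  rb2 <- crelu_bwd(p$bott$c2, cache$bott$b, g)
  rb1 <- crelu_bwd(p$bott$c1, cache$bott$a, rb2$gx)
  grads$bott <- list(c1 = list(W = rb1$gW, b = rb1$gb),
                     c2 = list(W = rb2$gW, b = rb2$gb))
  g <- rb1$gx
  for (l in rev(seq_len(d))) {
    ce <- cache$enc[[l]]
    gpool <- maxpool2_bwd(ce$idx, g) + gskip[[l]]
    r2 <- crelu_bwd(p$enc[[l]]$c2, ce$b, gpool)
    r1 <- crelu_bwd(p$enc[[l]]$c1, ce$a, r2$gx)
    grads$enc[[l]] <- list(c1 = list(W = r1$gW, b = r1$gb),
                           c2 = list(W = r2$gW, b = r2$gb))
    g <- r1$gx
  }
  grads
}

#' Apply a restoration model to an image
#'
#' The image is normalised to `[0, 1]` by its own maximum, passed through
#' the network, mapped back to the original intensity scale and clipped at
#' zero. Masks and metadata are carried through; the condition label becomes
#' `"dl"`.
#'
#' @param model a trained (or untrained) `unet_model`.
#' @param image a `phantom_image` or numeric matrix with sides divisible by
#'   `2^depth`.
#' @return restored image of the same type and shape as the input.
#' @export
apply_model <- function(model, image) {
  stopifnot(inherits(model, "unet_model"))
  x <- pixels_of(image)
  scale <- max(x)
  if (scale <= 0) scale <- 1
  y <- unet_forward(model, x / scale)$y * scale
  y[y < 0] <- 0
  rewrap_degraded(image, y, label = "dl")
}
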