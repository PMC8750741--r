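#' Training configuration for the restoration network
#'
#' @param epochs number of passes over the training partition.
#' @param batch_size images per gradient step (gradients averaged).
#' @param learning_rate Adam step size.
#' @param optimizer only `"adam"` is implemented.
#' @param seed integer seed controlling weight initialisation, shuffling and
#'   any noise draws; a fixed seed makes single-threaded runs bit-identical.
#' @param weights a [loss_weights()] for the mixed loss.
#' @param patch_mode `"full"`: whole slices are used as training samples.
#' @param selection_rule `"best_validation_total"`: the returned weights are
#'   those of the epoch with the lowest total validation loss.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 15L, batch_size = 4L, learning_rate = 1e-3,
                         optimizer = "adam", seed = 1L,
                         weights = loss_weights(),
                         patch_mode = "full",
                         selection_rule = "best_validation_total") {
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0)
    stop("epochs, batch_size and learning_rate must be positive", call. = FALSE)
  if (!identical(optimizer, "adam"))
    stop("only the adam optimizer is implemented", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), weights = weights,
                 patch_mode = patch_mode, selection_rule = selection_rule),
            class = "train_config")
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(v, skeleton) {
  utils::relist(v, utils::as.relistable(skeleton))
}

#' Train the restoration U-Net on degraded/reference pairs
#'
#' Minimises the mixed loss (MSE + weighted mean gradient error + weighted
#' MS-SSIM dissimilarity) with Adam over (degraded, reference) pairs built
#' from the cohort's train partition; the validation partition drives model
#' selection. Images are normalised to `[0, 1]` by the degraded input's
#' maximum. The run is fully seeded: weight initialisation, per-image noise
#' draws and epoch shuffles all derive from `tc$seed`.
#'
#' @param cohort a [generate_cohort()] result with non-empty train and
#'   validation partitions.
#' @param degradation a [degradation_config()] describing the simulated fast
#'   acquisition the model must invert.
#' @param spec a [unet_spec()].
#' @param tc a [train_config()].
#' @param verbose print one line per epoch.
#' @return a `unet_model` carrying `history` (one row per epoch with all
#'   loss components on train and validation) and the training manifest.
#' @export
train_model <- function(cohort, degradation, spec, tc = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(cohort, "phantom_cohort"),
            inherits(degradation, "degradation_config"),
            inherits(spec, "unet_spec"), inherits(tc, "train_config"))
  train_imgs <- cohort_subset(cohort, "train")
  val_imgs <- cohort_subset(cohort, "val")
  if (length(train_imgs) == 0 || length(val_imgs) == 0)
    stop("cohort must have non-empty train and validation partitions",
         call. = FALSE)

  make_pair <- function(img, i) {
    deg <- degrade(img, degradation, seed = degradation$seed + 7919L * i)
    s <- max(pixels_of(deg)); if (s <= 0) s <- 1
    list(x = pixels_of(deg) / s, y = pixels_of(img) / s)
  }
  train_pairs <- lapply(seq_along(train_imgs),
                        function(i) make_pair(train_imgs[[i]], i))
  val_pairs <- lapply(seq_along(val_imgs),
                      function(i) make_pair(val_imgs[[i]], 100000L + i))

  model <- unet_init(spec, seed = tc$seed)
  theta <- flatten_params(model$params)
  skeleton <- model$params
  m <- numeric(length(theta)); v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; t_step <- 0L

  eval_loss <- function(pairs) {
    comp <- vapply(pairs, function(p) {
      lv <- mix_loss(p$y, unet_forward(model, p$x)$y, tc$weights)
      c(lv$total, lv$mse, lv$mge, lv$ms_ssim_term)
    }, numeric(4))
    rowMeans(comp)
  }

  history <- vector("list", tc$epochs)
  best <- list(val = Inf, params = model$params, epoch = 0L)

  with_seed(tc$seed + 1L, {
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample(length(train_pairs))
      tr_acc <- c(0, 0, 0, 0); n_batches <- 0L
      for (start in seq(1, length(ord), by = tc$batch_size)) {
        idx <- ord[start:min(start + tc$batch_size - 1L, length(ord))]
        gsum <- NULL
        bl <- c(0, 0, 0, 0)
        for (i in idx) {
          p <- train_pairs[[i]]
          fw <- unet_forward(model, p$x, want_cache = TRUE)
          lg <- mix_loss_grad(p$y, fw$y, tc$weights)
          if (!is.finite(lg$value$total))
            stop(sprintf("training diverged (non-finite loss) at epoch %d",
                         epoch), call. = FALSE)
          grads <- unet_backward(model, fw$cache, lg$grad)
          gv <- flatten_params(grads)
          gsum <- if (is.null(gsum)) gv else gsum + gv
          bl <- bl + c(lg$value$total, lg$value$mse, lg$value$mge,
                       lg$value$ms_ssim_term)
        }
        gmean <- gsum / length(idx)
        t_step <- t_step + 1L
        m <- beta1 * m + (1 - beta1) * gmean
        v <- beta2 * v + (1 - beta2) * gmean^2
        mhat <- m / (1 - beta1^t_step)
        vhat <- v / (1 - beta2^t_step)
        theta <- theta - tc$learning_rate * mhat / (sqrt(vhat) + adam_eps)
        model$params <- unflatten_params(theta, skeleton)
        tr_acc <- tr_acc + bl / length(idx)
        n_batches <- n_batches + 1L
      }
      tr <- tr_acc / n_batches
      vl <- eval_loss(val_pairs)
      history[[epoch]] <- data.frame(
        epoch = epoch,
        train_total = tr[1], train_mse = tr[2], train_mge = tr[3],
        train_ms_ssim_term = tr[4],
        val_total = vl[1], val_mse = vl[2], val_mge = vl[3],
        val_ms_ssim_term = vl[4])
      if (vl[1] < best$val)
        best <- list(val = vl[1], params = model$params, epoch = epoch)
      if (verbose)
        message(sprintf("epoch %d: train %.5f, val %.5f", epoch, tr[1], vl[1]))
    }
  })

  model$params <- best$params
  model$history <- do.call(rbind, history)
  model$manifest <- list(
    train_config = unclass(tc)[setdiff(names(unclass(tc)), "weights")],
    loss_weights = unclass(tc$weights),
    degradation = unclass(degradation),
    spec = unclass(spec),
    selected_epoch = best$epoch,
    n_train = length(train_pairs), n_val = length(val_pairs),
    cohort_config_id = cohort$manifest$config_id)
  model
}
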