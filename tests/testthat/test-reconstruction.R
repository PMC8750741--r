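test_that("sobel gradient magnitude matches trivial and derived cases", {
  expect_equal(max(sobel_gradient_magnitude(matrix(3, 6, 6))), 0)

  # unit-slope ramp: interior response of the 3x3 kernel pair is 8
  ramp <- matrix(rep(1:12, each = 12), 12, 12)
  g <- sobel_gradient_magnitude(ramp)
  expect_true(all(abs(g[2:11, 2:11] - 8) < 1e-12))

  expect_error(sobel_gradient_magnitude(matrix(0, 2, 2)), "3x3")
})

test_that("sobel magnitude commutes with 90-degree rotation on interiors", {
  set.seed(41)
  x <- matrix(rnorm(100), 10, 10)
  rot90 <- function(m) t(m)[, nrow(m):1]
  g1 <- rot90(sobel_gradient_magnitude(x))
  g2 <- sobel_gradient_magnitude(rot90(x))
  expect_equal(g1[2:9, 2:9], g2[2:9, 2:9], tolerance = 1e-12)
})

test_that("sobel magnitude is absolutely homogeneous", {
  set.seed(42)
  x <- matrix(rnorm(64), 8, 8)
  for (a in c(-2.5, 0.5, 3)) {
    expect_equal(sobel_gradient_magnitude(a * x),
                 abs(a) * sobel_gradient_magnitude(x), tolerance = 1e-12)
  }
})

test_that("mixed loss satisfies its contract at the trivial points", {
  set.seed(17)
  x <- matrix(runif(16 * 16), 16, 16)
  lv <- mix_loss(x, x)
  expect_equal(lv$total, 0)
  expect_equal(lv$mse, 0)
  expect_equal(lv$mge, 0)
  expect_equal(lv$ms_ssim_term, 0)

  # constant 0 vs constant 1: mse is 1, gradients of constants vanish
  z <- matrix(0, 16, 16); o <- matrix(1, 16, 16)
  lv <- mix_loss(z, o)
  expect_equal(lv$mse, 1)
  expect_equal(lv$mge, 0)

  expect_error(mix_loss(matrix(0, 4, 4), matrix(0, 5, 5)), "dimensions")
})

test_that("mixed-loss analytic gradient matches finite differences", {
  set.seed(23)
  x <- matrix(runif(16 * 16), 16, 16)
  y <- x + matrix(rnorm(256, 0, 0.05), 16, 16)
  lg <- radistab:::mix_loss_grad(x, y)
  expect_equal(lg$value$total, mix_loss(x, y)$total, tolerance = 1e-12)
  eps <- 1e-6
  for (i in sample(256, 8)) {
    yp <- y; yp[i] <- yp[i] + eps
    ym <- y; ym[i] <- ym[i] - eps
    num <- (mix_loss(x, yp)$total - mix_loss(x, ym)$total) / (2 * eps)
    expect_equal(lg$grad[i], num, tolerance = 1e-4)
  }
})

test_that("ms_ssim behaves like a similarity", {
  set.seed(5)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_equal(ms_ssim(x, x), 1)

  # small mean offset with c^2 << c1 barely moves the value
  expect_gte(ms_ssim(x, x + 0.0005), 0.99)

  # structural inversion of a binary image is strongly dissimilar
  b <- matrix(rep(c(0, 1), length.out = 32 * 32), 32, 32)
  b[1:16, ] <- 0
  expect_lt(ms_ssim(b, 1 - b), 0.5)

  expect_error(ms_ssim(matrix(0, 4, 4), matrix(0, 4, 4)), "window")
})

test_that("scale count auto-reduces for small images", {
  expect_equal(radistab:::ms_ssim_n_scales(c(16, 16), 11L), 1L)
  expect_equal(radistab:::ms_ssim_n_scales(c(64, 64), 11L), 3L)
  expect_equal(radistab:::ms_ssim_n_scales(c(512, 512), 11L), 5L)
})

test_that("unet forward honours shape and residual contracts", {
  spec <- unet_spec(depth = 2L, base_channels = 4L)
  model <- unet_init(spec, seed = 2L)
  x <- matrix(runif(16 * 16), 16, 16)
  y <- radistab:::unet_forward(model, x)$y
  expect_equal(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  expect_error(radistab:::unet_forward(model, matrix(0, 15, 15)), "divisible")

  # zeroed final layer: the convolutional path contributes only its bias,
  # so the residual output equals input + bias
  model$params$final$W[] <- 0
  model$params$final$b[] <- 0.25
  y0 <- radistab:::unet_forward(model, x)$y
  expect_equal(y0, x + 0.25, tolerance = 1e-12)

  expect_error(unet_spec(use_batch_norm = TRUE), "batch normalisation")
})

test_that("unet parameter gradients match finite differences", {
  spec <- unet_spec(depth = 2L, base_channels = 3L)
  model <- unet_init(spec, seed = 4L)
  set.seed(9)
  x <- matrix(runif(16 * 16), 16, 16)
  gy <- matrix(rnorm(256), 16, 16)
  fw <- radistab:::unet_forward(model, x, want_cache = TRUE)
  gv <- radistab:::flatten_params(
    radistab:::unet_backward(model, fw$cache, gy))
  theta <- radistab:::flatten_params(model$params)
  eps <- 1e-6
  for (i in sample(length(theta), 10)) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    mp <- model; mp$params <- radistab:::unflatten_params(tp, model$params)
    mm <- model; mm$params <- radistab:::unflatten_params(tm, model$params)
    num <- sum((radistab:::unet_forward(mp, x)$y -
                  radistab:::unet_forward(mm, x)$y) * gy) / (2 * eps)
    expect_equal(gv[i], num, tolerance = 1e-4)
  }
})

test_that("seeded tiny training runs are reproducible and well-formed", {
  cfg <- phantom_config(matrix_size = 32L, n_lesions = 1L,
                        lesion_radius_range = c(3, 5),
                        baseline_noise_sigma = 0.5, seed = 77L)
  co <- generate_cohort(cfg, 12L, 2L)
  dg <- degradation_config("nex", kspace_sigma = 0.08, seed = 3L)
  tc <- train_config(epochs = 2L, batch_size = 4L, seed = 19L)
  sp <- unet_spec(depth = 2L, base_channels = 2L)
  m1 <- train_model(co, dg, sp, tc)
  m2 <- train_model(co, dg, sp, tc)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 2L)
  expect_true(all(is.finite(unlist(m1$history))))
  # loss decomposition holds exactly for every logged epoch
  for (side in c("train", "val")) {
    tot <- m1$history[[paste0(side, "_total")]]
    rec <- m1$history[[paste0(side, "_mse")]] +
      0.1 * m1$history[[paste0(side, "_mge")]] +
      0.1 * m1$history[[paste0(side, "_ms_ssim_term")]]
    expect_equal(tot, rec, tolerance = 1e-12)
  }
  # applying the model preserves shape, positivity and relabels
  test <- radistab:::cohort_subset(co, "test")[[1]]
  out <- apply_model(m1, test)
  expect_equal(dim(out$pixels), dim(test$pixels))
  expect_true(all(out$pixels >= 0))
  expect_identical(out$meta$condition, "dl")
})

test_that("training on the identity task drives validation MSE down sharply", {
  cfg <- phantom_config(matrix_size = 32L, n_lesions = 1L,
                        lesion_radius_range = c(3, 5),
                        baseline_noise_sigma = 0.5, seed = 78L)
  co <- generate_cohort(cfg, 14L, 2L)
  dg <- degradation_config("none")
  tc <- train_config(epochs = 4L, batch_size = 4L, seed = 20L)
  sp <- unet_spec(depth = 2L, base_channels = 2L)
  m <- train_model(co, dg, sp, tc)
  # identity input: the residual path must learn to emit ~zero correction
  expect_lt(m$history$val_mse[4], m$history$val_mse[1])
  expect_lt(min(m$history$val_mse), 1e-3)
})
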