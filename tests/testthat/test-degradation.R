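test_that("resolution degradation preserves size and loses Nyquist detail", {
  img <- generate_slice(small_phantom_config(seed = 3L))
  out <- degrade_resolution(img, 2L)
  expect_equal(dim(out$pixels), dim(img$pixels))
  expect_identical(out$lesion_masks, img$lesion_masks)
  expect_identical(out$meta$condition, "fast")

  # constant image passes through exactly
  const <- matrix(7.5, 16, 16)
  expect_equal(degrade_resolution(const, 2L), const, tolerance = 1e-12)

  # one-period-per-2-pixel checkerboard: detail is destroyed
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  out_cb <- degrade_resolution(cb, 2L)
  expect_lt(var(as.vector(out_cb)), 0.10 * var(as.vector(cb)))

  expect_error(degrade_resolution(matrix(0, 15, 15), 2L), "divisible")
})

test_that("resolution degradation never increases total variance", {
  for (seed in 1:4) {
    img <- generate_slice(small_phantom_config(seed = seed))
    for (f in c(2L, 4L)) {
      out <- degrade_resolution(img, f)
      expect_lte(var(as.vector(out$pixels)), var(as.vector(img$pixels)))
    }
  }
})

test_that("NEX degradation at zero sigma is the identity on magnitudes", {
  img <- generate_slice(small_phantom_config(seed = 9L))
  out <- degrade_nex(img, 0)
  expect_equal(out$pixels, img$pixels, tolerance = 1e-12)
  expect_identical(out$meta$condition, "fast")
  expect_error(degrade_nex(img, -0.1), ">= 0")
})

test_that("NEX degradation is deterministic given a seed and leaves masks alone", {
  img <- generate_slice(small_phantom_config(seed = 9L))
  a <- degrade_nex(img, 0.08, seed = 21L)
  b <- degrade_nex(img, 0.08, seed = 21L)
  cc <- degrade_nex(img, 0.08, seed = 22L)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, cc$pixels))
  expect_identical(a$lesion_masks, img$lesion_masks)
  expect_true(all(a$pixels >= 0))
})

test_that("background noise is Rayleigh with the implied image-domain sigma", {
  # all-zero image: unit fallback scale, so sigma_img = kspace_sigma
  s <- 0.25
  zero <- matrix(0, 320, 320)
  out <- degrade_nex(zero, s, seed = 31L)
  v <- as.vector(out)
  n <- length(v)
  expect_gte(n, 1e5)
  mean_expected <- s * sqrt(pi / 2)
  se <- s * sqrt(2 - pi / 2) / sqrt(n)
  expect_lt(abs(mean(v) - mean_expected), 3 * se)
  # goodness of fit against the Rayleigh CDF at alpha = 0.01
  ks <- stats::ks.test(v, function(q) 1 - exp(-q^2 / (2 * s^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("bright constant regions acquire Rician-mean intensities", {
  A <- 10
  img <- matrix(A, 320, 320)
  s_frac <- 0.05                     # scale = mean = A, so sigma_img = 0.5
  sigma <- s_frac * A
  out <- degrade_nex(img, s_frac, seed = 17L)
  v <- as.vector(out)
  mu <- rician_mean_oracle(A, sigma)
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - mu), 3 * se)
})

test_that("degradation dispatcher honours the configured mode", {
  img <- generate_slice(small_phantom_config(seed = 2L))
  cfg_r <- degradation_config("resolution", factor = 2L)
  cfg_n <- degradation_config("nex", kspace_sigma = 0.05, seed = 3L)
  cfg_0 <- degradation_config("none")
  expect_equal(degrade(img, cfg_r)$pixels, degrade_resolution(img, 2L)$pixels)
  expect_equal(degrade(img, cfg_n)$pixels,
               degrade_nex(img, 0.05, seed = 3L)$pixels)
  expect_identical(degrade(img, cfg_0)$pixels, img$pixels)
  expect_identical(degrade(img, cfg_0)$meta$condition, "fast")
})
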