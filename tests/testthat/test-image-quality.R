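test_that("psnr matches closed forms and the infinity sentinel", {
  x <- matrix(runif(64), 8, 8)
  expect_identical(psnr(x, x, 1), Inf)

  # MAXI = 1, MSE = 0.01 -> 20 dB
  y <- x
  y[] <- x + 0.1
  expect_equal(psnr(x, y, 1), 20, tolerance = 1e-12)

  # MAXI = 255, MSE = 1 -> 48.1308 dB
  z <- x + 1
  expect_equal(round(psnr(x, z, 255), 4), 48.1308)

  expect_error(psnr(x, matrix(0, 4, 4), 1), "dimensions")
  expect_error(psnr(x, x, 0), "max_value")
})

test_that("psnr decreases monotonically with noise level", {
  set.seed(12)
  x <- generate_slice(small_phantom_config(seed = 12L))$pixels
  sigmas <- c(1, 2, 4, 8, 16)
  vals <- vapply(sigmas, function(s)
    psnr(x, x + matrix(rnorm(length(x), 0, s), nrow(x)), 255), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("ssim matches a naive windowed oracle on random pairs", {
  set.seed(33)
  for (r in 1:20) {
    x <- matrix(runif(144), 12, 12)
    y <- x + matrix(rnorm(144, 0, 0.1), 12, 12)
    got <- ssim(x, y, 1, window = 5L)
    expect_equal(got, naive_ssim(x, y, 1, win = 5L), tolerance = 1e-9)
  }
})

test_that("difference maps implement the percent formula with exclusions", {
  ref <- matrix(10, 8, 8)
  mask <- matrix(FALSE, 8, 8); mask[3:6, 3:6] <- TRUE

  d0 <- difference_map(ref, ref, mask, 255)
  expect_equal(d0$mean, 0)
  expect_equal(max(d0$map, na.rm = TRUE), 0)

  d5 <- difference_map(1.05 * ref, ref, mask, 255)
  expect_equal(unique(round(d5$map[mask], 10)), 5)
  expect_equal(d5$mean, 5, tolerance = 1e-10)

  # zero-reference pixels are excluded and counted
  ref2 <- ref; ref2[3, 3] <- 0
  dx <- difference_map(ref, ref2, mask, 255)
  expect_equal(dx$n_excluded, 1)
  expect_equal(dx$n, sum(mask) - 1)

  expect_error(difference_map(ref, matrix(0, 8, 8), mask, 255), "empty ROI")
})

test_that("difference-map summaries are recomputable from the raw map", {
  set.seed(8)
  img <- generate_slice(small_phantom_config(seed = 8L))
  post <- img$pixels * (1 + matrix(rnorm(length(img$pixels), 0, 0.05),
                                   nrow(img$pixels)))
  for (m in img$lesion_masks) {
    d <- difference_map(post, img$pixels, m, 255)
    inc <- d$map[!is.na(d$map)]
    expect_equal(d$mean, mean(inc), tolerance = 1e-12)
    expect_equal(d$sd, sd(inc), tolerance = 1e-12)
  }
})

test_that("roi statistics behave on constant, two-bin, and denoised inputs", {
  img <- matrix(5, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  rs <- roi_stats(img, mask)
  expect_equal(rs$cv, 0)
  expect_equal(rs$entropy, 0)

  # two equal-count bins one bin-width apart -> exactly 1 bit
  img2 <- matrix(rep(c(0, 30), 50), 10, 10)
  rs2 <- roi_stats(img2, mask, bin_width = 25)
  expect_equal(rs2$entropy, 1)

  # averaging i.i.d. noise must strictly reduce CV
  set.seed(21)
  noisy <- 100 + matrix(rnorm(400, 0, 20), 20, 20)
  sm <- (noisy[seq(1, 19, 2), seq(1, 19, 2)] + noisy[seq(2, 20, 2), seq(1, 19, 2)] +
           noisy[seq(1, 19, 2), seq(2, 20, 2)] + noisy[seq(2, 20, 2), seq(2, 20, 2)]) / 4
  cv_raw <- roi_stats(noisy, matrix(TRUE, 20, 20))$cv
  cv_avg <- roi_stats(sm, matrix(TRUE, 10, 10))$cv
  expect_lt(cv_avg, cv_raw)

  expect_error(roi_stats(img, matrix(FALSE, 10, 10)), "empty")
  expect_error(roi_stats(img - 5, mask), "zero")
})
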