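test_that("slice generation is deterministic and structurally valid", {
  cfg <- small_phantom_config(seed = 11L)
  img1 <- generate_slice(cfg)
  img2 <- generate_slice(cfg)
  expect_identical(img1$pixels, img2$pixels)
  expect_identical(img1$lesion_masks, img2$lesion_masks)

  expect_true(all(is.finite(img1$pixels)))
  expect_true(all(img1$pixels >= 0))
  frac <- mean(img1$meta$head_mask)
  expect_gt(frac, 0.40)
  expect_lt(frac, 0.80)
  for (m in img1$lesion_masks) {
    expect_gte(sum(m), 9)
    expect_true(all(img1$meta$head_mask[m]))
  }
  expect_identical(img1$meta$condition, "reference")
})

test_that("a lesion-free configuration still produces a head", {
  img <- generate_slice(small_phantom_config(n_lesions = 0L))
  expect_length(img$lesion_masks, 0)
  expect_gt(mean(img$meta$head_mask), 0.4)
})

test_that("configured lesion contrast is recovered without noise", {
  for (contrast in c(1.5, 2.0, 2.5)) {
    cfg <- phantom_config(matrix_size = 64L, n_lesions = 2L,
                          lesion_radius_range = c(3, 6),
                          lesion_contrast = contrast,
                          baseline_noise_sigma = 0, seed = 23L)
    img <- generate_slice(cfg)
    m_par <- mean(img$pixels[img$meta$parenchyma_mask])
    for (m in img$lesion_masks) {
      ratio <- mean(img$pixels[m]) / m_par
      expect_lt(abs(ratio - contrast) / contrast, 0.05)
    }
  }
})

test_that("lesion masks are connected regions", {
  img <- generate_slice(small_phantom_config(seed = 31L))
  # flood fill from one mask pixel must reach the whole mask
  for (m in img$lesion_masks) {
    idx <- which(m, arr.ind = TRUE)
    reached <- matrix(FALSE, nrow(m), ncol(m))
    stack <- list(idx[1, ])
    reached[idx[1, 1], idx[1, 2]] <- TRUE
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1] + di; j <- p[2] + dj
        if (i >= 1 && i <= nrow(m) && j >= 1 && j <= ncol(m) &&
            m[i, j] && !reached[i, j]) {
          reached[i, j] <- TRUE
          stack[[length(stack) + 1]] <- c(i, j)
        }
      }
    }
    expect_equal(sum(reached), sum(m))
  }
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(matrix_size = 63L), "even")
  expect_error(phantom_config(lesion_contrast = 0.9), "lesion_contrast")
  expect_error(phantom_config(lesion_radius_range = c(1, 5)), "radii")
  expect_error(phantom_config(baseline_noise_sigma = -1), "baseline_noise")
})

test_that("cohort partition follows the stated rounding rule", {
  cfg <- small_phantom_config(seed = 5L)
  co <- generate_cohort(cfg, 10L, 2L)
  sz <- co$manifest$partition_sizes
  # round(6.8) = 7 train, floor(1.7) = 1 val, remainder 2 test
  expect_equal(unlist(sz), c(train = 7, val = 1, test = 2))
  expect_equal(length(co$images), 10L)
  expect_equal(as.vector(table(co$partition)), c(7, 1, 2))
  expect_match(co$manifest$rounding_rule, "round")
})

test_that("cohorts are exhaustive, disjoint, and reproducible", {
  cfg <- small_phantom_config(seed = 13L)
  co1 <- generate_cohort(cfg, 12L, 3L)
  co2 <- generate_cohort(cfg, 12L, 3L)
  expect_equal(length(co1$images), 12L)
  expect_equal(length(co1$partition), 12L)
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(co1$images[[5]]$pixels, co2$images[[5]]$pixels)
  # per-image seeds all distinct -> images differ
  expect_false(identical(co1$images[[1]]$pixels, co1$images[[2]]$pixels))
})

test_that("unreachable test-lesion demands raise a configuration error", {
  cfg <- small_phantom_config(n_lesions = 1L)
  expect_error(generate_cohort(cfg, 10L, 50L), "cannot reach")
})
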