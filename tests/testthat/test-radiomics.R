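test_that("catalog has the expected class structure and counts", {
  cat_df <- build_catalog()
  expect_equal(nrow(cat_df), 104L)
  expect_equal(unique(cat_df$class),
               c("Intensity", "GLCM", "GLDM", "GLRLM", "GLSZM", "NGTDM",
                 "IQ-wavelets"))
  counts <- table(cat_df$class)[unique(cat_df$class)]
  expect_equal(as.vector(counts), c(27L, 24L, 14L, 16L, 16L, 5L, 2L))
  expect_equal(cat_df$feature[cat_df$class == "NGTDM"],
               paste0("ngtdm_", c("Busyness", "Coarseness", "Complexity",
                                  "Contrast", "Strength")))
  expect_equal(sort(cat_df$feature[cat_df$class == "IQ-wavelets"]),
               c("IQwavelet_global", "IQwavelet_local"))
  # bespoke intensity names and the duplicated entries are both present
  expect_true(all(c("Min", "Max", "Peak", "CV(%)", "MaxOnMeanRing",
                    "firstorder_Minimum", "firstorder_Maximum",
                    "Kurtosis", "firstorder_Kurtosis") %in% cat_df$feature))
  expect_false(any(duplicated(cat_df$feature)))
  expect_identical(build_catalog(), cat_df)  # stable ordering
})

test_that("degenerate single-gray-level regions use the defined conventions", {
  img <- matrix(5, 16, 16)
  mask <- matrix(FALSE, 16, 16); mask[5:10, 5:10] <- TRUE
  fv <- extract_features(img, mask)
  expect_equal(unname(fv["firstorder_Variance"]), 0)
  expect_equal(unname(fv["firstorder_Entropy"]), 0)
  expect_equal(unname(fv["glcm_Contrast"]), 0)
  expect_equal(unname(fv["glrlm_GrayLevelNonUniformityNormalized"]), 1)
  expect_true(all(is.finite(fv)))
})

test_that("distance-1 GLCM contrast on a two-level checkerboard matches the
           hand-enumerated value under angle averaging", {
  # 4x4 checkerboard alternating 10 and 60 (level difference d = 2 at bin
  # width 25). Horizontal and vertical angles see only unequal pairs
  # (contrast d^2); both diagonals see only equal pairs (contrast 0); the
  # angle-averaged contrast is d^2 / 2.
  img <- outer(1:4, 1:4, function(i, j) ifelse((i + j) %% 2 == 0, 10, 60))
  mask <- matrix(TRUE, 4, 4)
  fv <- extract_features(img, mask,
                         extraction_settings(bin_width = 25))
  d <- 2
  expect_equal(unname(fv["glcm_Contrast"]), d^2 / 2, tolerance = 1e-12)
})

test_that("first-order summaries equal direct recomputation on masked pixels", {
  img <- generate_slice(small_phantom_config(seed = 44L, noise = 0.5))
  m <- img$lesion_masks[[1]]
  v <- img$pixels[m]
  fv <- extract_features(img, m)
  expect_equal(unname(fv["firstorder_Mean"]), mean(v))
  expect_equal(unname(fv["Min"]), min(v))
  expect_equal(unname(fv["Max"]), max(v))
  expect_equal(unname(fv["firstorder_Median"]), median(v))
  expect_equal(unname(fv["firstorder_Energy"]), sum(v^2))
  expect_equal(unname(fv["firstorder_Variance"]), mean((v - mean(v))^2))
  expect_equal(unname(fv["CV(%)"]),
               100 * sqrt(mean((v - mean(v))^2)) / mean(v))
  expect_equal(unname(fv["firstorder_10Percentile"]),
               unname(quantile(v, 0.1)))
})

test_that("intensity features are shift-covariant as documented", {
  img <- generate_slice(small_phantom_config(seed = 45L, noise = 0.5))
  m <- img$lesion_masks[[1]]
  c_shift <- 40
  f0 <- extract_features(img, m)
  f1 <- extract_features(img$pixels + c_shift, m)
  for (feat in c("Mean", "Median", "firstorder_Minimum",
                 "firstorder_Maximum", "firstorder_10Percentile",
                 "firstorder_90Percentile"))
    expect_equal(unname(f1[feat]), unname(f0[feat]) + c_shift,
                 tolerance = 1e-10)
  # variance and fixed-bin-width entropy are shift-invariant
  expect_equal(unname(f1["firstorder_Variance"]),
               unname(f0["firstorder_Variance"]), tolerance = 1e-10)
  expect_equal(unname(f1["firstorder_Entropy"]),
               unname(f0["firstorder_Entropy"]), tolerance = 1e-10)
})

test_that("every generated phantom ROI yields a complete finite vector", {
  for (seed in c(101L, 102L, 103L)) {
    img <- generate_slice(small_phantom_config(seed = seed, noise = 0.5))
    for (m in img$lesion_masks) {
      fv <- extract_features(img, m)
      expect_length(fv, 104L)
      expect_identical(names(fv), build_catalog()$feature)
      expect_true(all(is.finite(fv)))
    }
  }
})

test_that("gray levels with no pairs along an angle do not break GLCM", {
  # the single 200-valued pixel has neighbours only in some directions, so
  # per-angle co-occurrence matrices carry empty rows for its level
  img <- matrix(10, 4, 4)
  img[1, 2] <- 60; img[3, 1] <- 60; img[2, 3] <- 60
  img[3, 4] <- 200
  fv <- extract_features(img, matrix(TRUE, 4, 4))
  expect_true(all(is.finite(fv)))
})

test_that("too-small masks are rejected", {
  img <- matrix(runif(64), 8, 8)
  m <- matrix(FALSE, 8, 8); m[4, 4] <- TRUE
  expect_error(extract_features(img, m), "too small")
})

test_that("iq wavelet ratio separates smooth, Nyquist and noisy content", {
  expect_equal(iq_wavelet(matrix(4, 16, 16), scope = "global"), 0)

  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_gt(iq_wavelet(cb, scope = "global"), 10)

  set.seed(50)
  img <- generate_slice(small_phantom_config(seed = 50L))$pixels
  noisy <- img + matrix(rnorm(length(img), 0, 5), nrow(img))
  expect_gt(iq_wavelet(noisy, scope = "global"),
            iq_wavelet(img, scope = "global"))

  expect_error(iq_wavelet(matrix(0, 1, 4), scope = "global"), "too small")
})

test_that("local iq wavelet follows the lesion bounding box", {
  img <- generate_slice(small_phantom_config(seed = 51L, noise = 0.5))
  m <- img$lesion_masks[[1]]
  loc <- iq_wavelet(img, m, scope = "local")
  glob <- iq_wavelet(img, scope = "global")
  expect_true(is.finite(loc) && loc >= 0)
  expect_false(isTRUE(all.equal(loc, glob)))
})

test_that("feature vectors carry provenance attributes", {
  img <- generate_slice(small_phantom_config(seed = 52L))
  fv <- extract_features(img, img$lesion_masks[[1]],
                         lesion_id = 3L)
  expect_identical(attr(fv, "condition"), "reference")
  expect_identical(attr(fv, "lesion_id"), 3L)
  expect_match(attr(fv, "settings_id"), "bin_width=25")
})
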