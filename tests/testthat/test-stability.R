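test_that("lin_ccc matches its defining cases", {
  expect_equal(lin_ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  # frozen brute-force value: 2*(2/3) / ((2/3)+(2/3)+100)
  expect_equal(lin_ccc(c(1, 2, 3), c(11, 12, 13)), 2 * (2 / 3) / (4 / 3 + 100))
  expect_equal(lin_ccc(c(1, 2, 3), c(11, 12, 13)), 0.0131578947368,
               tolerance = 1e-10)
  expect_error(lin_ccc(c(1, 1), c(1, 1)), "undefined")
  expect_error(lin_ccc(1, c(1, 2)), "equal length")
})

test_that("lin_ccc agrees with a naive moment oracle on random samples", {
  set.seed(61)
  for (r in 1:100) {
    n <- sample(5:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- 0.5 * x + rnorm(n, mean = runif(1, -1, 1))
    expect_equal(lin_ccc(x, y), naive_ccc(x, y), tolerance = 1e-12)
  }
})

test_that("ccc magnitude never exceeds Pearson |r|", {
  set.seed(62)
  for (r in 1:200) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- runif(1, -2, 2) * x + rnorm(n, sd = runif(1, 0.1, 2)) + runif(1, -3, 3)
    expect_lte(abs(lin_ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
})

make_toy_table <- function(n_lesions = 8, seed = 1, fast_noise = 0,
                           dl_noise = 0) {
  # feature table over the full catalog with per-feature lesion-level values
  set.seed(seed)
  catalog <- build_catalog()
  rows <- list()
  for (f in catalog$feature) {
    base <- rnorm(n_lesions, mean = runif(1, 1, 10), sd = runif(1, 0.5, 2))
    fast <- base + rnorm(n_lesions, 0, fast_noise)
    dl <- base + rnorm(n_lesions, 0, dl_noise)
    rows[[length(rows) + 1]] <- data.frame(
      lesion = rep(seq_len(n_lesions), 3),
      condition = rep(c("reference", "fast", "dl"), each = n_lesions),
      feature = f, value = c(base, fast, dl))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("paired_feature_table", "data.frame")
  out
}

test_that("identity reconstruction yields all-stable features with CCC 1", {
  tab <- make_toy_table(seed = 3)
  res <- paired_feature_stats(tab, "dl_vs_ref")
  expect_equal(nrow(res), 104L)
  expect_true(all(res$stable))
  expect_true(all(res$ccc == 1))
  # zero-variance differences: paired t undefined, reported not fatal
  expect_true(all(is.na(res$paired_t_p)))
  expect_true(all(grepl("zero-variance", res$note)))
})

test_that("the 0.85 stability threshold is inclusive and monotone", {
  # construct a pair with CCC exactly 0.85: y = x shifted by delta where
  # 2*sx2/(2*sx2 + delta^2) = 0.85 -> delta = sqrt(2*sx2*0.15/0.85)
  x <- c(1, 2, 3, 4, 5)
  sx2 <- mean((x - mean(x))^2)
  delta <- sqrt(2 * sx2 * 0.15 / 0.85)
  expect_equal(lin_ccc(x, x + delta), 0.85, tolerance = 1e-12)

  tab <- make_toy_table(n_lesions = 5, seed = 4)
  f1 <- tab$feature[1]
  sel <- tab$feature == f1 & tab$condition == "dl"
  ref <- tab$value[tab$feature == f1 & tab$condition == "reference"]
  s2 <- mean((ref - mean(ref))^2)
  tab$value[sel] <- ref + sqrt(2 * s2 * 0.15 / 0.85)
  res <- paired_feature_stats(tab, "dl_vs_ref", threshold = 0.85)
  expect_true(res$stable[res$feature == f1])

  # raising the threshold can only remove stability, never add it
  res_hi <- paired_feature_stats(tab, "dl_vs_ref", threshold = 0.95)
  expect_true(all(res_hi$stable <= res$stable))
})

test_that("features drown under added noise and get flagged unstable", {
  tab <- make_toy_table(n_lesions = 30, seed = 5, fast_noise = 50)
  res <- paired_feature_stats(tab, "fast_vs_ref")
  # noise sd 50 vastly exceeds the base sd (<= 2): CCC collapses
  expect_gt(mean(!res$stable), 0.95)
  tab2 <- make_toy_table(n_lesions = 30, seed = 5, fast_noise = 0.01)
  res2 <- paired_feature_stats(tab2, "fast_vs_ref")
  expect_gt(mean(res2$stable), 0.95)
})

test_that("restoration summary counts match hand enumeration", {
  tab <- make_toy_table(seed = 6)
  rf <- paired_feature_stats(tab, "fast_vs_ref")
  rd <- paired_feature_stats(tab, "dl_vs_ref")

  # identical results -> zero restored
  s0 <- restoration_summary(rf, rf)
  expect_equal(s0$restored[s0$class == "overall"], 0)

  # hand-set pattern: first 10 features unstable in fast, stable in dl
  rf2 <- rf; rf2$stable[1:10] <- FALSE; rf2$ccc[1:10] <- 0.2
  s1 <- restoration_summary(rf2, rd)
  ov <- s1[s1$class == "overall", ]
  expect_equal(ov$unstable_fast, 10)
  expect_equal(ov$restored, 10)
  expect_equal(ov$pct_restored, 100 * 10 / 104)
  # all-unstable fast, all-stable dl -> 100% restored per class and overall
  rf3 <- rf; rf3$stable[] <- FALSE
  s2 <- restoration_summary(rf3, rd)
  expect_true(all(s2$pct_restored == 100))
})

test_that("linear model scoring equals a brute-force dot product", {
  spec0 <- linear_model_spec("null", weights = c("Mean" = 0), intercept = 1.5)
  img <- generate_slice(small_phantom_config(seed = 70L))
  fv <- extract_features(img, img$lesion_masks[[1]])
  expect_equal(apply_predictive_model(fv, spec0), 1.5)

  spec1 <- linear_model_spec("one", weights = c("Mean" = 1), intercept = 2)
  expect_equal(apply_predictive_model(fv, spec1), 2 + unname(fv["Mean"]))

  set.seed(71)
  feats <- sample(build_catalog()$feature, 6)
  w <- setNames(rnorm(6), feats)
  spec2 <- linear_model_spec("rand", weights = w, intercept = -0.3)
  expect_equal(apply_predictive_model(fv, spec2),
               -0.3 + sum(w * as.numeric(fv[feats])), tolerance = 1e-12)

  expect_error(linear_model_spec("bad", weights = c(NotAFeature = 1)),
               "unknown catalog")
  expect_error(apply_predictive_model(fv[1:5], spec2), "lacks")
})

test_that("bland_altman recovers trivial and simulated offsets", {
  s <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(s, s)
  expect_equal(ba0$mean_difference, 0)
  expect_true(ba0$degenerate)

  ba5 <- bland_altman(s, s + 0.5)
  expect_equal(ba5$mean_difference, 0.5)
  expect_equal(ba5$sd_difference, 0)
  expect_true(ba5$degenerate)
  expect_true(is.na(ba5$p_value))

  # limits bracket the mean difference
  set.seed(80)
  ref <- rnorm(40, 10, 2)
  post <- ref - 0.86 + rnorm(40, 0, 0.4)
  ba <- bland_altman(ref, post)
  expect_lt(ba$loa_lower, ba$mean_difference)
  expect_gt(ba$loa_upper, ba$mean_difference)
  se <- 0.4 / sqrt(40)
  expect_lt(abs(ba$mean_difference - (-0.86)), 2 * se)
  expect_lt(ba$p_value, 0.001)
  expect_equal(nrow(ba$data), 40)

  expect_error(bland_altman(1:4, 1:5), "paired")
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})
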