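# First-order intensity features over the masked pixels, including the
# bespoke entries (Min, Max, Peak, CV(%), MaxOnMeanRing) and the
# firstorder_* duplicates kept as distinct catalog entries.

dilate3x3 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  out <- matrix(FALSE, n, m)
  for (di in -1:1) for (dj in -1:1) {
    i_dst <- seq(max(1, 1 + di), min(n, n + di))
    j_dst <- seq(max(1, 1 + dj), min(m, m + dj))
    out[i_dst, j_dst] <- out[i_dst, j_dst] |
      mask[i_dst - di, j_dst - dj, drop = FALSE]
  }
  out
}

# mean of the 3x3 neighbourhood around every pixel (border-clipped)
local_mean3 <- function(image) {
  n <- nrow(image); m <- ncol(image)
  s <- matrix(0, n, m); cnt <- matrix(0, n, m)
  for (di in -1:1) for (dj in -1:1) {
    i_dst <- seq(max(1, 1 + di), min(n, n + di))
    j_dst <- seq(max(1, 1 + dj), min(m, m + dj))
    s[i_dst, j_dst] <- s[i_dst, j_dst] + image[i_dst - di, j_dst - dj]
    cnt[i_dst, j_dst] <- cnt[i_dst, j_dst] + 1
  }
  s / cnt
}

firstorder_features <- function(image, mask, settings) {
  v <- image[mask]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  q <- quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  lv <- discretize(v, settings)
  p <- tabulate(lv) / n
  p <- p[p > 0]
  robust <- v[v >= q[1] & v <= q[5]]

  peak <- max(local_mean3(image)[mask])
  ring <- dilate3x3(mask) & !mask
  ring_mean <- if (any(ring)) mean(image[ring]) else mean(v)
  max_on_ring <- if (ring_mean != 0) max(v) / ring_mean else Inf

  skewness <- if (m2 > 0) m3 / m2^1.5 else 0
  kurtosis <- if (m2 > 0) m4 / m2^2 else 0   # non-excess form

  c("Min" = min(v),
    "Max" = max(v),
    "Peak" = peak,
    "Mean" = mu,
    "Median" = q[3],
    "Skewness" = skewness,
    "Kurtosis" = kurtosis,
    "CV(%)" = 100 * sqrt(m2) / mu,
    "MaxOnMeanRing" = max_on_ring,
    "firstorder_10Percentile" = q[1],
    "firstorder_90Percentile" = q[5],
    "firstorder_Energy" = sum(v^2),
    "firstorder_Entropy" = -sum(p * log2(p)),
    "firstorder_InterquartileRange" = q[4] - q[2],
    "firstorder_Kurtosis" = kurtosis,
    "firstorder_Maximum" = max(v),
    "firstorder_MeanAbsoluteDeviation" = mean(abs(v - mu)),
    "firstorder_Mean" = mu,
    "firstorder_Median" = q[3],
    "firstorder_Minimum" = min(v),
    "firstorder_Range" = max(v) - min(v),
    "firstorder_RobustMeanAbsoluteDeviation" =
      mean(abs(robust - mean(robust))),
    "firstorder_RootMeanSquared" = sqrt(mean(v^2)),
    "firstorder_Skewness" = skewness,
    "firstorder_TotalEnergy" = sum(v^2),   # unit pixel area
    "firstorder_Uniformity" = sum(p^2),
    "firstorder_Variance" = m2)
}
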