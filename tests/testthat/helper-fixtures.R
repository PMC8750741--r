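# Shared fixtures and independent oracle implementations. Oracles are
# deliberately naive (explicit loops, direct formulas) and never call the
# package code paths they check.

small_phantom_config <- function(seed = 7L, noise = 0, n_lesions = 2L) {
  phantom_config(matrix_size = 64L, n_lesions = n_lesions,
                 lesion_radius_range = c(3, 6), lesion_contrast = 2.0,
                 baseline_noise_sigma = noise, seed = seed)
}

# direct double-loop SSIM: per-window statistics computed explicitly
naive_ssim <- function(x, y, L, win = 5L, sigma = 1.5) {
  ax <- seq_len(win) - (win + 1) / 2
  k <- exp(-ax^2 / (2 * sigma^2))
  w <- outer(k, k); w <- w / sum(w)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  vals <- c()
  for (i in seq_len(nrow(x) - win + 1)) {
    for (j in seq_len(ncol(x) - win + 1)) {
      px <- x[i:(i + win - 1), j:(j + win - 1)]
      py <- y[i:(i + win - 1), j:(j + win - 1)]
      mx <- sum(w * px); my <- sum(w * py)
      vx <- sum(w * px^2) - mx^2; vy <- sum(w * py^2) - my^2
      cxy <- sum(w * px * py) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# direct per-pixel Sobel magnitude with replicate borders
naive_sobel <- function(x) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- t(kx)
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  at <- function(i, j) x[min(max(i, 1), n), min(max(j, 1), m)]
  for (i in seq_len(n)) for (j in seq_len(m)) {
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      gx <- gx + kx[di + 2, dj + 2] * at(i + di, j + dj)
      gy <- gy + ky[di + 2, dj + 2] * at(i + di, j + dj)
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

# Lin's concordance from the definition, via explicit sums
naive_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my)) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# numeric Rician mean through direct integration of the density
# (exponentially-scaled Bessel avoids overflow at large A/sigma)
rician_mean_oracle <- function(A, sigma) {
  g <- function(x) x * x / sigma^2 *
    exp(-(x - A)^2 / (2 * sigma^2)) *
    besselI(x * A / sigma^2, 0, expon.scaled = TRUE)
  stats::integrate(g, 0, A + 12 * sigma, rel.tol = 1e-10)$value
}

# cached heavyweight artifacts for the trained-model checks: built once per
# test run, reused across test files
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_runs <- function() {
  if (!is.null(.acceptance_cache$runs)) return(.acceptance_cache$runs)
  runs <- list()
  for (mode in c("resolution", "nex")) {
    cfg <- experiment_config(
      degradation = degradation_config(mode, factor = 2L, kspace_sigma = 0.08),
      seed = 20251001L)
    runs[[mode]] <- run_experiment(cfg)
  }
  .acceptance_cache$runs <- runs
  runs
}
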