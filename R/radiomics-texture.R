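# Texture-matrix features on the discretized masked image. All matrices are
# 2D (per-slice); gray levels are the actual discretized values, so
# level-weighted features (Low/HighGrayLevelEmphasis etc.) use the true
# level numbers, not re-indexed ranks. Logarithms use log2 with the machine
# epsilon guard; 0 log 0 = 0 throughout.

EPS <- 2.220446e-16

# crop the discretized image to the mask bounding box; NA outside the mask
crop_levels <- function(image, mask, settings) {
  v <- image[mask]
  lv_vals <- discretize(v, settings)
  lv <- matrix(NA_integer_, nrow(image), ncol(image))
  lv[mask] <- lv_vals
  ri <- range(which(rowSums(!is.na(lv)) > 0))
  ci <- range(which(colSums(!is.na(lv)) > 0))
  lv[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
}

texture_offsets <- function(d) {
  list(c(0L, d), c(d, 0L), c(d, d), c(d, -d))
}

offset_pairs <- function(lv, dr, dc) {
  nr <- nrow(lv); nc <- ncol(lv)
  i1 <- seq(max(1, 1 - dr), min(nr, nr - dr))
  j1 <- seq(max(1, 1 - dc), min(nc, nc - dc))
  if (length(i1) == 0 || length(j1) == 0) return(NULL)
  a <- lv[i1, j1, drop = FALSE]
  b <- lv[i1 + dr, j1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  cbind(a[ok], b[ok])
}

## ---- GLCM ------------------------------------------------------------

glcm_matrix <- function(lv, lvls, dr, dc) {
  pr <- offset_pairs(lv, dr, dc)
  if (is.null(pr)) return(NULL)
  K <- length(lvls)
  ia <- match(pr[, 1], lvls); ib <- match(pr[, 2], lvls)
  cnt <- matrix(tabulate((ib - 1L) * K + ia, nbins = K * K), K, K)
  cnt <- cnt + t(cnt)                      # symmetric
  cnt / sum(cnt)
}

glcm_features_one <- function(P, gl) {
  # a level can have no pairs along this angle: drop its empty row/column
  # (matrix is symmetric) so marginals never divide by zero
  occ <- rowSums(P) > 0
  P <- P[occ, occ, drop = FALSE]
  gl <- gl[occ]
  K <- length(gl)
  Ng <- max(gl)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(gl * px); mu_y <- sum(gl * py)
  sx2 <- sum((gl - mu_x)^2 * px); sy2 <- sum((gl - mu_y)^2 * py)
  GI <- matrix(gl, K, K); GJ <- t(GI)
  D <- GI - GJ; S <- GI + GJ
  autoc <- sum(P * GI * GJ)
  corr <- if (sx2 > 0 && sy2 > 0)
    (autoc - mu_x * mu_y) / sqrt(sx2 * sy2) else 1
  cs <- S - mu_x - mu_y

  dvals <- sort(unique(abs(D)))
  pd <- vapply(dvals, function(k) sum(P[abs(D) == k]), numeric(1))
  da <- sum(dvals * pd)
  svals <- sort(unique(S))
  ps <- vapply(svals, function(k) sum(P[S == k]), numeric(1))

  hxy <- -sum(P[P > 0] * log2(P[P > 0]))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * log2(pxy + EPS))
  hxy2 <- -sum(pxy[pxy > 0] * log2(pxy[pxy > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))

  mcc <- if (K == 1) 1 else {
    Q <- matrix(0, K, K)
    for (kk in seq_len(K))
      Q <- Q + outer(P[, kk] / px, P[, kk] / py[kk])
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }

  c(Autocorrelation = autoc,
    ClusterProminence = sum(P * cs^4),
    ClusterShade = sum(P * cs^3),
    ClusterTendency = sum(P * cs^2),
    Contrast = sum(P * D^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    DifferenceVariance = sum((dvals - da)^2 * pd),
    Id = sum(P / (1 + abs(D))),
    Idm = sum(P / (1 + D^2)),
    Idmn = sum(P / (1 + D^2 / Ng^2)),
    Idn = sum(P / (1 + abs(D) / Ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[D != 0] / D[D != 0]^2),
    JointAverage = mu_x,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(svals * ps),
    SumEntropy = -sum(ps[ps > 0] * log2(ps[ps > 0])),
    SumSquares = sx2)
}

glcm_features <- function(lv, settings) {
  lvls <- sort(unique(lv[!is.na(lv)]))
  res <- list()
  for (off in texture_offsets(settings$distance)) {
    P <- glcm_matrix(lv, lvls, off[1], off[2])
    if (!is.null(P)) res[[length(res) + 1]] <- glcm_features_one(P, lvls)
  }
  out <- rowMeans(do.call(cbind, res))    # feature values averaged over angles
  setNames(out, paste0("glcm_", names(out)))
}

## ---- GLRLM -----------------------------------------------------------

matrix_lines <- function(lv, dir) {
  switch(dir,
         h = lapply(seq_len(nrow(lv)), function(i) lv[i, ]),
         v = lapply(seq_len(ncol(lv)), function(j) lv[, j]),
         d = split(lv, row(lv) - col(lv)),
         a = split(lv, row(lv) + col(lv)))
}

run_lengths <- function(line) {
  x <- ifelse(is.na(line), -1L, line)
  r <- rle(x)
  keep <- r$values != -1L
  cbind(level = r$values[keep], len = r$lengths[keep])
}

glrlm_features_one <- function(R, gl, rl, n_pix) {
  nr <- sum(R)
  p <- R / nr
  GI <- matrix(gl, length(gl), length(rl)); RJ <- matrix(rl, length(gl),
                                                         length(rl), byrow = TRUE)
  r_i <- rowSums(R); r_j <- colSums(R)
  mu_i <- sum(p * GI); mu_j <- sum(p * RJ)
  c(GrayLevelNonUniformity = sum(r_i^2) / nr,
    GrayLevelNonUniformityNormalized = sum(r_i^2) / nr^2,
    GrayLevelVariance = sum(p * (GI - mu_i)^2),
    HighGrayLevelRunEmphasis = sum(p * GI^2),
    LongRunEmphasis = sum(p * RJ^2),
    LongRunHighGrayLevelEmphasis = sum(p * GI^2 * RJ^2),
    LongRunLowGrayLevelEmphasis = sum(p * RJ^2 / GI^2),
    LowGrayLevelRunEmphasis = sum(p / GI^2),
    RunEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    RunLengthNonUniformity = sum(r_j^2) / nr,
    RunLengthNonUniformityNormalized = sum(r_j^2) / nr^2,
    RunPercentage = nr / n_pix,
    RunVariance = sum(p * (RJ - mu_j)^2),
    ShortRunEmphasis = sum(p / RJ^2),
    ShortRunHighGrayLevelEmphasis = sum(p * GI^2 / RJ^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (GI^2 * RJ^2)))
}

glrlm_features <- function(lv, settings) {
  n_pix <- sum(!is.na(lv))
  lvls <- sort(unique(lv[!is.na(lv)]))
  res <- list()
  for (dir in c("h", "v", "d", "a")) {
    runs <- do.call(rbind, lapply(matrix_lines(lv, dir), run_lengths))
    if (is.null(runs) || nrow(runs) == 0) next
    rls <- seq_len(max(runs[, "len"]))
    R <- matrix(0, length(lvls), length(rls))
    for (r in seq_len(nrow(runs))) {
      i <- match(runs[r, "level"], lvls)
      R[i, runs[r, "len"]] <- R[i, runs[r, "len"]] + 1
    }
    res[[length(res) + 1]] <- glrlm_features_one(R, lvls, rls, n_pix)
  }
  out <- rowMeans(do.call(cbind, res))
  setNames(out, paste0("glrlm_", names(out)))
}

## ---- GLSZM -----------------------------------------------------------

# connected zones (8-connectivity) of equal discretized level
glszm_zones <- function(lv) {
  nr <- nrow(lv); nc <- ncol(lv)
  seen <- is.na(lv)
  zones <- list()
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (seen[i0, j0]) next
    lev <- lv[i0, j0]
    stack <- (j0 - 1L) * nr + i0
    seen[i0, j0] <- TRUE
    size <- 0L
    while (length(stack) > 0) {
      idx <- stack[length(stack)]; stack <- stack[-length(stack)]
      size <- size + 1L
      i <- (idx - 1L) %% nr + 1L; j <- (idx - 1L) %/% nr + 1L
      for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (!seen[ii, jj] && lv[ii, jj] == lev) {
          seen[ii, jj] <- TRUE
          stack <- c(stack, (jj - 1L) * nr + ii)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = lev, size = size)
  }
  do.call(rbind, zones)
}

glszm_features <- function(lv, settings) {
  n_pix <- sum(!is.na(lv))
  z <- glszm_zones(lv)
  lvls <- sort(unique(z[, "level"]))
  szs <- seq_len(max(z[, "size"]))
  Z <- matrix(0, length(lvls), length(szs))
  for (r in seq_len(nrow(z)))
    Z[match(z[r, "level"], lvls), z[r, "size"]] <-
      Z[match(z[r, "level"], lvls), z[r, "size"]] + 1
  nz <- sum(Z)
  p <- Z / nz
  GI <- matrix(lvls, length(lvls), length(szs))
  SJ <- matrix(szs, length(lvls), length(szs), byrow = TRUE)
  z_i <- rowSums(Z); z_s <- colSums(Z)
  mu_i <- sum(p * GI); mu_s <- sum(p * SJ)
  out <- c(GrayLevelNonUniformity = sum(z_i^2) / nz,
           GrayLevelNonUniformityNormalized = sum(z_i^2) / nz^2,
           GrayLevelVariance = sum(p * (GI - mu_i)^2),
           HighGrayLevelZoneEmphasis = sum(p * GI^2),
           LargeAreaEmphasis = sum(p * SJ^2),
           LargeAreaHighGrayLevelEmphasis = sum(p * GI^2 * SJ^2),
           LargeAreaLowGrayLevelEmphasis = sum(p * SJ^2 / GI^2),
           LowGrayLevelZoneEmphasis = sum(p / GI^2),
           SizeZoneNonUniformity = sum(z_s^2) / nz,
           SizeZoneNonUniformityNormalized = sum(z_s^2) / nz^2,
           SmallAreaEmphasis = sum(p / SJ^2),
           SmallAreaHighGrayLevelEmphasis = sum(p * GI^2 / SJ^2),
           SmallAreaLowGrayLevelEmphasis = sum(p / (GI^2 * SJ^2)),
           ZoneEntropy = -sum(p[p > 0] * log2(p[p > 0])),
           ZonePercentage = nz / n_pix,
           ZoneVariance = sum(p * (SJ - mu_s)^2))
  setNames(out, paste0("glszm_", names(out)))
}

## ---- GLDM ------------------------------------------------------------

gldm_features <- function(lv, settings) {
  nr <- nrow(lv); nc <- ncol(lv)
  d <- settings$distance
  inm <- !is.na(lv)
  # dependence count: qualifying neighbours within Chebyshev distance d,
  # plus one for the centre pixel
  dep <- matrix(0L, nr, nc)
  for (dj in -d:d) for (di in -d:d) {
    if (di == 0 && dj == 0) next
    i_dst <- seq(max(1, 1 + di), min(nr, nr + di))
    j_dst <- seq(max(1, 1 + dj), min(nc, nc + dj))
    a <- lv[i_dst, j_dst, drop = FALSE]
    b <- lv[i_dst - di, j_dst - dj, drop = FALSE]
    q <- !is.na(a) & !is.na(b) & abs(a - b) <= settings$gldm_alpha
    dep[i_dst, j_dst] <- dep[i_dst, j_dst] + q
  }
  lev <- lv[inm]; dpc <- dep[inm] + 1L
  lvls <- sort(unique(lev))
  djs <- seq_len(max(dpc))
  D <- matrix(0, length(lvls), length(djs))
  for (r in seq_along(lev)) {
    i <- match(lev[r], lvls)
    D[i, dpc[r]] <- D[i, dpc[r]] + 1
  }
  nz <- sum(D)
  p <- D / nz
  GI <- matrix(lvls, length(lvls), length(djs))
  DJ <- matrix(djs, length(lvls), length(djs), byrow = TRUE)
  d_i <- rowSums(D); d_j <- colSums(D)
  mu_i <- sum(p * GI); mu_j <- sum(p * DJ)
  out <- c(DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0])),
           DependenceNonUniformity = sum(d_j^2) / nz,
           DependenceNonUniformityNormalized = sum(d_j^2) / nz^2,
           DependenceVariance = sum(p * (DJ - mu_j)^2),
           GrayLevelNonUniformity = sum(d_i^2) / nz,
           GrayLevelVariance = sum(p * (GI - mu_i)^2),
           HighGrayLevelEmphasis = sum(p * GI^2),
           LargeDependenceEmphasis = sum(p * DJ^2),
           LargeDependenceHighGrayLevelEmphasis = sum(p * GI^2 * DJ^2),
           LargeDependenceLowGrayLevelEmphasis = sum(p * DJ^2 / GI^2),
           LowGrayLevelEmphasis = sum(p / GI^2),
           SmallDependenceEmphasis = sum(p / DJ^2),
           SmallDependenceHighGrayLevelEmphasis = sum(p * GI^2 / DJ^2),
           SmallDependenceLowGrayLevelEmphasis = sum(p / (GI^2 * DJ^2)))
  setNames(out, paste0("gldm_", names(out)))
}

## ---- NGTDM -----------------------------------------------------------

ngtdm_features <- function(lv, settings) {
  nr <- nrow(lv); nc <- ncol(lv)
  d <- settings$distance
  inm <- !is.na(lv)
  nb_sum <- matrix(0, nr, nc); nb_cnt <- matrix(0, nr, nc)
  for (dj in -d:d) for (di in -d:d) {
    if (di == 0 && dj == 0) next
    i_dst <- seq(max(1, 1 + di), min(nr, nr + di))
    j_dst <- seq(max(1, 1 + dj), min(nc, nc + dj))
    b <- lv[i_dst - di, j_dst - dj, drop = FALSE]
    ok <- !is.na(b)
    add <- b; add[!ok] <- 0
    nb_sum[i_dst, j_dst] <- nb_sum[i_dst, j_dst] + add
    nb_cnt[i_dst, j_dst] <- nb_cnt[i_dst, j_dst] + ok
  }
  use <- inm & nb_cnt > 0
  lev <- lv[use]
  abar <- nb_sum[use] / nb_cnt[use]
  dev <- abs(lev - abar)
  lvls <- sort(unique(lev))
  n_i <- vapply(lvls, function(l) sum(lev == l), numeric(1))
  s_i <- vapply(lvls, function(l) sum(dev[lev == l]), numeric(1))
  np <- sum(n_i)
  p_i <- n_i / np
  ngp <- length(lvls)

  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(p_i, p_i) * outer(lvls, lvls, "-")^2) /
      (ngp * (ngp - 1)) * sum(s_i) / np
  } else 0
  busy_den <- sum(abs(outer(lvls * p_i, lvls * p_i, "-")))
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  PS <- outer(p_i * s_i, p_i * s_i, "+")
  PP <- outer(p_i, p_i, "+")
  DD <- abs(outer(lvls, lvls, "-"))
  complexity <- sum(DD * PS / PP) / np
  strength_den <- sum(s_i)
  strength <- if (strength_den > 0)
    sum(PP * outer(lvls, lvls, "-")^2) / strength_den else 0

  c(ngtdm_Busyness = busyness,
    ngtdm_Coarseness = coarseness,
    ngtdm_Complexity = complexity,
    ngtdm_Contrast = contrast,
    ngtdm_Strength = strength)
}
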