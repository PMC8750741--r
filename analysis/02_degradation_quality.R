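#!/usr/bin/env Rscript

# Stage 2 — fast-acquisition simulation, before any restoration.
#
# Applies both degradations (acquisition-matrix halving; NEX halving via
# complex Gaussian k-space noise) to the test partition and grades them
# against the reference with PSNR and SSIM, plus lesion-ROI difference
# maps, CV and entropy. Also verifies the noise family: signal-free
# background after the NEX route should be Rayleigh.

suppressPackageStartupMessages(library(radistab))
dir.create("results", showWarnings = FALSE)

cfg <- experiment_config(seed = 1L)
cohort <- generate_cohort(cfg$phantom, cfg$n_images, cfg$n_test_lesions)
test_imgs <- cohort$images[cohort$partition == "test"]
imax <- cfg$phantom$intensity_max

rows <- list()
for (mode in c("resolution", "nex")) {
  dg <- degradation_config(mode, factor = 2L, kspace_sigma = 0.08,
                           seed = 1000L)
  for (i in seq_along(test_imgs)) {
    ref <- test_imgs[[i]]
    fast <- degrade(ref, dg, seed = 1000L + i)
    dm <- difference_map(fast$pixels, ref$pixels, ref$lesion_masks[[1]], imax)
    rs <- roi_stats(fast, ref$lesion_masks[[1]])
    rows[[length(rows) + 1]] <- data.frame(
      mode = mode, image = i,
      psnr = psnr(ref$pixels, fast$pixels, imax),
      ssim = ssim(ref$pixels, fast$pixels, imax),
      lesion_diff_pct = dm$mean, lesion_cv = rs$cv,
      lesion_entropy = rs$entropy)
  }
}
quality <- do.call(rbind, rows)
write.csv(quality, "results/degraded_quality.csv", row.names = FALSE)

for (mode in unique(quality$mode)) {
  q <- quality[quality$mode == mode, ]
  cat(sprintf("%-10s PSNR %5.2f +/- %4.2f dB, SSIM %.3f +/- %.3f, lesion diff %4.2f%%\n",
              mode, mean(q$psnr), sd(q$psnr), mean(q$ssim), sd(q$ssim),
              mean(q$lesion_diff_pct)))
}

s <- 0.2
bg <- as.vector(degrade_nex(matrix(0, 320, 320), s, seed = 99L))
cat(sprintf("background Rayleigh check: mean/expected = %.4f (n = %d)\n",
            mean(bg) / (s * sqrt(pi / 2)), length(bg)))
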