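#!/usr/bin/env Rscript

# Stage 4 — headline report.
#
# Reads the persisted stage outputs of analysis/03_experiments.R and
# renders the headline aggregates: per-comparison unstable counts and
# percentages, per-class restoration, the wavelet CCCs under the noise
# route, and the Bland-Altman statistics of the model scores. Writes
# results/headline.md.

dir.create("results", showWarnings = FALSE)
lines <- c("# Radiomic stability under fast-MRI simulation - headline results",
           "")

for (mode in c("resolution", "nex")) {
  run_dir <- file.path("results", paste0("run_", mode))
  if (!dir.exists(run_dir))
    stop("missing ", run_dir, "; run analysis/03_experiments.R first")
  st_f <- read.csv(file.path(run_dir, "stability_fast_vs_ref.csv"))
  st_d <- read.csv(file.path(run_dir, "stability_dl_vs_ref.csv"))
  summ <- read.csv(file.path(run_dir, "summary_by_class.csv"))
  q <- read.csv(file.path(run_dir, "quality.csv"))
  man <- jsonlite::read_json(file.path(run_dir, "run_manifest.json"))

  lines <- c(lines, sprintf("## %s mode", mode), "",
             sprintf("- image quality (n = %d test images): PSNR %.2f dB (fast) vs %.2f dB (restored); SSIM %.3f vs %.3f",
                     nrow(q), mean(q$psnr_fast), mean(q$psnr_dl),
                     mean(q$ssim_fast), mean(q$ssim_dl)),
             sprintf("- significantly different features (paired t, p < 0.05): %d/104 fast, %d/104 restored",
                     sum(st_f$paired_t_p < 0.05, na.rm = TRUE),
                     sum(st_d$paired_t_p < 0.05, na.rm = TRUE)),
             sprintf("- unstable features (CCC < 0.85): %d/104 (%.2f%%) fast, %d/104 (%.2f%%) restored",
                     sum(!st_f$stable), 100 * sum(!st_f$stable) / 104,
                     sum(!st_d$stable), 100 * sum(!st_d$stable) / 104),
             "", "per-class restoration:", "")
  for (i in seq_len(nrow(summ))) {
    lines <- c(lines, sprintf("  - %-12s n=%3d unstable fast %2d, restored %2d (%.0f%%)",
                              summ$class[i], summ$n[i], summ$unstable_fast[i],
                              summ$restored[i], summ$pct_restored[i]))
  }
  for (feat in c("IQwavelet_local", "IQwavelet_global")) {
    lines <- c(lines, sprintf("  - %s CCC: %.3f fast -> %.3f restored", feat,
                              st_f$ccc[st_f$feature == feat],
                              st_d$ccc[st_d$feature == feat]))
  }
  lines <- c(lines, "", "Bland-Altman of linear model scores (post - ref):", "")
  for (m in man$bland_altman) {
    lines <- c(lines, sprintf("  - %s: mean diff %.3f (fast) vs %.3f (restored)",
                              m$name, m$fast$mean_difference,
                              m$dl$mean_difference))
  }
  lines <- c(lines, "")
}

writeLines(lines, "results/headline.md")
cat(paste(lines, collapse = "\n"), "\n")
cat("wrote results/headline.md\n")
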