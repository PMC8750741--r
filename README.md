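# radistab

**Radiomic feature stability under fast-MRI simulation and deep-learning
restoration.**

Quantitative imaging models — radiomics — extract intensity and texture
features from lesion regions of interest and feed them into predictive
models. New MRI systems ship deep-learning (DL) reconstruction that lets
scans run roughly twice as fast, either with half the acquisition matrix
(lower resolution) or half the number of excitations, NEX (more noise).
`radistab` is an end-to-end, fully synthetic testbed for the question this
raises for anyone deploying radiomic models on such images: **which
radiomic features survive fast acquisition, and does DL restoration bring
the lost ones back?**

The package provides, as tested R code:

- a seeded **phantom generator** for post-Gd T1-like 2D brain slices with
  hyperintense lesion masks (no patient data needed anywhere);
- the two **fast-acquisition simulators**: acquisition-matrix halving
  (bilinear down/up-sampling) and NEX halving (complex Gaussian noise in
  k-space, giving Rician image noise — Rayleigh in background);
- a batch-norm-free **residual U-Net** with training implemented from
  scratch (RcppArmadillo; analytic gradients, Adam), minimising the mixed
  loss

  `Mix(Y, Ŷ) = MSE(Y, Ŷ) + 0.1·MGE(G(Y), G(Ŷ)) + 0.1·(1 − MS-SSIM(Y, Ŷ))`

  where `G` is the Sobel gradient magnitude and MS-SSIM the multi-scale
  structural similarity;
- **image-quality metrics**: PSNR (`10·log10(MAXI²/MSE)`), SSIM/MS-SSIM,
  lesion difference maps (`|post − ref|/ref·100`), ROI CV and entropy;
- a **104-feature radiomic engine** (first-order intensity incl. bespoke
  Peak/CV(%)/MaxOnMeanRing, GLCM, GLDM, GLRLM, GLSZM, NGTDM, and two
  Haar-wavelet image-quality features);
- the **stability statistics**: per-feature paired t-tests, Pearson r,
  Lin's concordance correlation coefficient
  `CCC = 2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²)` with the inclusive 0.85
  stability threshold, per-class restoration summaries, linear
  radiomic-model scoring and Bland–Altman agreement.

## Worked example

```r
library(radistab)

cfg <- experiment_config(
  degradation = degradation_config("nex", kspace_sigma = 0.08),
  seed = 1L)
res <- run_experiment(cfg, verbose = TRUE)
print(res)

q <- res$quality
cat(sprintf("PSNR fast %.2f -> DL %.2f dB; SSIM fast %.3f -> DL %.3f\n",
            mean(q$psnr_fast), mean(q$psnr_dl),
            mean(q$ssim_fast), mean(q$ssim_dl)))
subset(res$summary, class == "overall")
```

With the default desk-scale study conditions (440 phantoms of 64×64 with
one lesion each, ≈300 training images, a depth-3 base-8 residual U-Net
trained 8 epochs for the denoising task) and seed 1 this prints:

```
<experiment_result: 92/104 features unstable (fast), 80/104 (restored), 12 restored>
PSNR fast 32.55 -> DL 39.05 dB; SSIM fast 0.842 -> DL 0.978
    class   n unstable_fast unstable_dl restored degenerate pct_unstable_fast pct_unstable_dl pct_restored
8 overall 104            92          80       12          0          88.46154        76.92308     11.53846
```

Reading: halving the NEX destabilises most of the 104 features on these
small synthetic lesions (CCC < 0.85 against the reference); the trained
denoiser raises image quality by 6.5 dB and restores a subset of features,
most visibly the wavelet image-quality features — direct noise readouts —
whose CCC collapses on fast images (0.17 local, 0.45 global at seed 1) and
climbs after restoration (0.50 and 0.98). `res$models` holds the
Bland–Altman agreement of the two bundled linear model scores for the same
comparisons. Desk-scale texture features are harsher judges than
clinical-scale analyses (smaller lesions mean fewer pixels and fewer gray
levels per ROI), so absolute unstable counts sit higher here; the
direction of every effect — quality gain, feature loss under fast
acquisition, partial restoration, wavelet collapse and recovery — is the
finding.

The numbered scripts under `analysis/` run the same study as a pipeline
(cohort → degradation quality → both experiments → headline report) and
persist every stage under `results/`.

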