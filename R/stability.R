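#' Lin's concordance correlation coefficient
#'
#' Agreement measure for paired measurements: `2 s_xy / (s_x^2 + s_y^2 +
#' (mean(x) - mean(y))^2)` with population (1/n) moments and no bias
#' correction. Equals 1 for perfect concordance, -1 for perfect reversed
#' concordance about equal means/variances, and 0 for no correlation. Its
#' magnitude never exceeds Pearson's |r|.
#'
#' @param x,y numeric vectors of equal length >= 2 with finite values.
#' @return CCC in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must be paired samples of equal length >= 2", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- sx2 + sy2 + (mx - my)^2
  if (den == 0)
    stop("CCC undefined: both samples constant with equal means", call. = FALSE)
  2 * sxy / den
}

#' Per-feature stability statistics between two image conditions
#'
#' For every catalog feature, compares the per-lesion values of the two
#' conditions with a two-sided paired t-test, Pearson correlation, and Lin's
#' CCC; a feature is called stable when its CCC reaches the threshold
#' (inclusive: a CCC of exactly 0.85 is stable). Degenerate features
#' (zero-variance differences or undefined CCC) are reported with `NA`
#' statistics and a note, never as fatal errors; their `stable` call is
#' `NA` — neither stable nor unstable.
#'
#' @param table a `paired_feature_table` from [extract_feature_table()].
#' @param comparison `"fast_vs_ref"` or `"dl_vs_ref"`.
#' @param threshold minimum CCC for stability (default 0.85).
#' @return a data.frame of class `stability_result`: `feature`, `class`,
#'   `paired_t_p`, `pearson_r`, `ccc`, `stable`, `comparison`, `note`.
#' @export
paired_feature_stats <- function(table,
                                 comparison = c("fast_vs_ref", "dl_vs_ref"),
                                 threshold = 0.85) {
  comparison <- match.arg(comparison)
  cond <- if (comparison == "fast_vs_ref") "fast" else "dl"
  catalog <- build_catalog()
  need <- c("reference", cond)
  missing_cond <- setdiff(need, unique(table$condition))
  if (length(missing_cond) > 0)
    stop("table lacks condition(s): ", paste(missing_cond, collapse = ", "),
         call. = FALSE)

  res <- lapply(seq_len(nrow(catalog)), function(i) {
    feat <- catalog$feature[i]
    sub <- table[table$feature == feat, ]
    xr <- sub$value[sub$condition == "reference"][order(sub$lesion[sub$condition == "reference"])]
    xp <- sub$value[sub$condition == cond][order(sub$lesion[sub$condition == cond])]
    if (length(xr) != length(xp) || length(xr) < 2)
      stop(sprintf("incomplete pairs for feature '%s'", feat), call. = FALSE)
    note <- ""
    d <- xp - xr
    p_t <- if (all(d == 0)) {
      note <- "zero-variance differences; paired t undefined"
      NA_real_
    } else if (sd(d) == 0) {
      note <- "constant nonzero difference; paired t degenerate"
      NA_real_
    } else t.test(xp, xr, paired = TRUE)$p.value
    r <- if (sd(xr) == 0 || sd(xp) == 0) {
      note <- paste0(note, if (nzchar(note)) "; ", "constant feature")
      NA_real_
    } else cor(xr, xp)
    ccc <- tryCatch(lin_ccc(xr, xp), error = function(e) {
      note <<- paste0(note, if (nzchar(note)) "; ", conditionMessage(e))
      NA_real_
    })
    data.frame(feature = feat, class = catalog$class[i], paired_t_p = p_t,
               pearson_r = r, ccc = ccc,
               stable = if (is.na(ccc)) NA else ccc >= threshold,
               comparison = comparison, note = note, row.names = NULL)
  })
  out <- do.call(rbind, res)
  attr(out, "threshold") <- threshold
  class(out) <- c("stability_result", "data.frame")
  out
}

#' Restoration summary across feature classes
#'
#' Counts unstable features (CCC below threshold) under the fast and
#' restored conditions, and features *restored* by the model (unstable in
#' fast, stable after restoration), per class and overall, with percentages
#' over the class size and the full catalog. Degenerate features (undefined
#' CCC, `stable = NA`) are counted separately and excluded from the
#' unstable/restored tallies.
#'
#' @param results_fast,results_dl `stability_result` tables from
#'   [paired_feature_stats()] for the fast and restored comparisons.
#' @param catalog the feature catalog (defaults to [build_catalog()]).
#' @return a data.frame with one row per class plus an `"overall"` row:
#'   `n`, `unstable_fast`, `unstable_dl`, `restored` and the matching
#'   percentages.
#' @export
restoration_summary <- function(results_fast, results_dl,
                                catalog = build_catalog()) {
  if (!identical(results_fast$feature, catalog$feature) ||
      !identical(results_dl$feature, catalog$feature))
    stop("stability results do not cover the catalog in order", call. = FALSE)
  unstable_f <- !results_fast$stable   # NA stays NA (degenerate)
  unstable_d <- !results_dl$stable
  restored <- unstable_f & results_dl$stable
  one <- function(sel, label) {
    data.frame(class = label, n = sum(sel),
               unstable_fast = sum(unstable_f[sel], na.rm = TRUE),
               unstable_dl = sum(unstable_d[sel], na.rm = TRUE),
               restored = sum(restored[sel], na.rm = TRUE),
               degenerate = sum(is.na(unstable_f[sel]) |
                                  is.na(unstable_d[sel])),
               pct_unstable_fast =
                 100 * sum(unstable_f[sel], na.rm = TRUE) / sum(sel),
               pct_unstable_dl =
                 100 * sum(unstable_d[sel], na.rm = TRUE) / sum(sel),
               pct_restored = 100 * sum(restored[sel], na.rm = TRUE) / sum(sel))
  }
  rows <- lapply(unique(catalog$class),
                 function(cl) one(catalog$class == cl, cl))
  rows[[length(rows) + 1]] <- one(rep(TRUE, nrow(catalog)), "overall")
  do.call(rbind, rows)
}

#' Linear radiomic predictive-model specification
#'
#' A configurable linear scorer over catalog features:
#' `score = intercept + sum(weight * standardized value)`, with optional
#' per-feature standardisation `(x - center) / scale`.
#'
#' @param name model name.
#' @param weights named numeric vector; names must be catalog features.
#' @param intercept scalar.
#' @param standardize optional list with named numeric vectors `center` and
#'   `scale` covering the weighted features.
#' @return an object of class `linear_model_spec`.
#' @export
linear_model_spec <- function(name, weights, intercept = 0,
                              standardize = NULL) {
  catalog <- build_catalog()
  bad <- setdiff(names(weights), catalog$feature)
  if (length(bad) > 0)
    stop("unknown catalog feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(name = name, weights = weights, intercept = intercept,
                 standardize = standardize),
            class = "linear_model_spec")
}

#' Score one feature vector with a linear radiomic model
#'
#' @param fv a `feature_vector` (or named numeric vector).
#' @param spec a [linear_model_spec()].
#' @return the scalar score.
#' @export
apply_predictive_model <- function(fv, spec) {
  stopifnot(inherits(spec, "linear_model_spec"))
  miss <- setdiff(names(spec$weights), names(fv))
  if (length(miss) > 0)
    stop("feature vector lacks model feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  v <- as.numeric(fv[names(spec$weights)])
  if (!is.null(spec$standardize)) {
    v <- (v - spec$standardize$center[names(spec$weights)]) /
      spec$standardize$scale[names(spec$weights)]
  }
  spec$intercept + sum(spec$weights * v)
}

#' Bundled synthetic predictive-model fixtures
#'
#' Two linear model specifications over catalog features, standing in for
#' clinical survival and classification radiomic models whose coefficients
#' are not publicly available. The weights are arbitrary but documented;
#' the fixtures exercise the scoring and agreement machinery, they are not
#' clinical models.
#'
#' @return named list of two [linear_model_spec()] objects.
#' @export
predictive_model_fixtures <- function() {
  list(
    survival_synthetic = linear_model_spec(
      "survival_synthetic",
      weights = c("firstorder_Entropy" = 0.9,
                  "firstorder_Skewness" = 0.4,
                  "glcm_JointEntropy" = 0.6,
                  "glrlm_RunEntropy" = -0.5,
                  "ngtdm_Coarseness" = -0.7),
      intercept = 0.2),
    classification_synthetic = linear_model_spec(
      "classification_synthetic",
      weights = c("firstorder_Kurtosis" = 0.5,
                  "glcm_MCC" = 1.1,
                  "glszm_ZonePercentage" = -0.8,
                  "gldm_DependenceEntropy" = 0.35),
      intercept = -0.1))
}

# Standardisation parameters (center/scale per weighted feature) estimated
# from the reference condition of a feature table; scale floors at a small
# epsilon so constant features cannot produce infinities.
standardize_from_reference <- function(spec, table) {
  feats <- names(spec$weights)
  center <- scale_ <- setNames(numeric(length(feats)), feats)
  for (f in feats) {
    v <- table$value[table$feature == f & table$condition == "reference"]
    center[f] <- mean(v)
    scale_[f] <- max(sd(v), 1e-12)
  }
  spec$standardize <- list(center = center, scale = scale_)
  spec
}

# Per-lesion model scores for one condition of a feature table.
model_scores <- function(spec, table, condition) {
  lesions <- sort(unique(table$lesion))
  vapply(lesions, function(l) {
    sub <- table[table$lesion == l & table$condition == condition, ]
    fv <- setNames(sub$value, sub$feature)
    apply_predictive_model(fv, spec)
  }, numeric(1))
}

#' Bland-Altman agreement of paired scores
#'
#' Differences are `post - ref`; limits of agreement are
#' `mean difference +/- 1.96 sd`. The p-value is a two-sided one-sample
#' t-test of zero mean difference (`NA`, flagged degenerate, when the
#' differences have zero variance).
#'
#' @param scores_ref,scores_post paired numeric vectors (n >= 3).
#' @return a list of class `bland_altman_result`: `mean_difference`,
#'   `sd_difference`, `loa_lower`, `loa_upper`, `p_value`, `degenerate`,
#'   and plot-ready `data` (per-pair mean and difference).
#' @export
bland_altman <- function(scores_ref, scores_post) {
  if (length(scores_ref) != length(scores_post))
    stop("scores must be paired", call. = FALSE)
  if (length(scores_ref) < 3)
    stop("Bland-Altman needs at least 3 pairs", call. = FALSE)
  d <- scores_post - scores_ref
  md <- mean(d); sdd <- sd(d)
  degenerate <- sdd == 0
  p <- if (degenerate) NA_real_ else t.test(d)$p.value
  structure(list(mean_difference = md, sd_difference = sdd,
                 loa_lower = md - 1.96 * sdd, loa_upper = md + 1.96 * sdd,
                 p_value = p, degenerate = degenerate,
                 data = data.frame(mean = (scores_ref + scores_post) / 2,
                                   difference = d)),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.4f (sd %.4f), LoA [%.4f, %.4f], p = %s\n",
              x$mean_difference, x$sd_difference, x$loa_lower, x$loa_upper,
              if (is.na(x$p_value)) "NA (degenerate)" else
                format.pval(x$p_value, digits = 3)))
  invisible(x)
}
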