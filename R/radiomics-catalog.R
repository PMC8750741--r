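#' The 104-entry radiomic feature catalog
#'
#' Ordered catalog of the features extracted from each lesion region of
#' interest on each image condition: 27 first-order intensity features
#' (including the bespoke Min, Max, Peak, CV(%) and MaxOnMeanRing entries,
#' and the `firstorder_*` duplicates of Min/Max/Mean/Median/Skewness/
#' Kurtosis, which are kept as distinct catalog entries), 24 gray-level
#' co-occurrence (GLCM), 14 gray-level dependence (GLDM), 16 run-length
#' (GLRLM), 16 size-zone (GLSZM) and 5 neighbourhood gray-tone difference
#' (NGTDM) features, plus two wavelet-based image-quality features (local =
#' lesion region only, global = whole image).
#'
#' @return a data.frame of class `feature_catalog` with columns `class` and
#'   `feature`, in stable order, 104 rows.
#' @export
build_catalog <- function() {
  intensity <- c("Min", "Max", "Peak", "Mean", "Median", "Skewness",
                 "Kurtosis", "CV(%)", "MaxOnMeanRing",
                 "firstorder_10Percentile", "firstorder_90Percentile",
                 "firstorder_Energy", "firstorder_Entropy",
                 "firstorder_InterquartileRange", "firstorder_Kurtosis",
                 "firstorder_Maximum", "firstorder_MeanAbsoluteDeviation",
                 "firstorder_Mean", "firstorder_Median",
                 "firstorder_Minimum", "firstorder_Range",
                 "firstorder_RobustMeanAbsoluteDeviation",
                 "firstorder_RootMeanSquared", "firstorder_Skewness",
                 "firstorder_TotalEnergy", "firstorder_Uniformity",
                 "firstorder_Variance")
  glcm <- paste0("glcm_", c("Autocorrelation", "ClusterProminence",
                            "ClusterShade", "ClusterTendency", "Contrast",
                            "Correlation", "DifferenceAverage",
                            "DifferenceEntropy", "DifferenceVariance", "Id",
                            "Idm", "Idmn", "Idn", "Imc1", "Imc2",
                            "InverseVariance", "JointAverage", "JointEnergy",
                            "JointEntropy", "MCC", "MaximumProbability",
                            "SumAverage", "SumEntropy", "SumSquares"))
  gldm <- paste0("gldm_", c("DependenceEntropy", "DependenceNonUniformity",
                            "DependenceNonUniformityNormalized",
                            "DependenceVariance", "GrayLevelNonUniformity",
                            "GrayLevelVariance", "HighGrayLevelEmphasis",
                            "LargeDependenceEmphasis",
                            "LargeDependenceHighGrayLevelEmphasis",
                            "LargeDependenceLowGrayLevelEmphasis",
                            "LowGrayLevelEmphasis", "SmallDependenceEmphasis",
                            "SmallDependenceHighGrayLevelEmphasis",
                            "SmallDependenceLowGrayLevelEmphasis"))
  glrlm <- paste0("glrlm_", c("GrayLevelNonUniformity",
                              "GrayLevelNonUniformityNormalized",
                              "GrayLevelVariance", "HighGrayLevelRunEmphasis",
                              "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
                              "LongRunLowGrayLevelEmphasis",
                              "LowGrayLevelRunEmphasis", "RunEntropy",
                              "RunLengthNonUniformity",
                              "RunLengthNonUniformityNormalized",
                              "RunPercentage", "RunVariance",
                              "ShortRunEmphasis",
                              "ShortRunHighGrayLevelEmphasis",
                              "ShortRunLowGrayLevelEmphasis"))
  glszm <- paste0("glszm_", c("GrayLevelNonUniformity",
                              "GrayLevelNonUniformityNormalized",
                              "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
                              "LargeAreaEmphasis",
                              "LargeAreaHighGrayLevelEmphasis",
                              "LargeAreaLowGrayLevelEmphasis",
                              "LowGrayLevelZoneEmphasis",
                              "SizeZoneNonUniformity",
                              "SizeZoneNonUniformityNormalized",
                              "SmallAreaEmphasis",
                              "SmallAreaHighGrayLevelEmphasis",
                              "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
                              "ZonePercentage", "ZoneVariance"))
  ngtdm <- paste0("ngtdm_", c("Busyness", "Coarseness", "Complexity",
                              "Contrast", "Strength"))
  iq <- c("IQwavelet_global", "IQwavelet_local")
  cat_df <- rbind(
    data.frame(class = "Intensity", feature = intensity),
    data.frame(class = "GLCM", feature = glcm),
    data.frame(class = "GLDM", feature = gldm),
    data.frame(class = "GLRLM", feature = glrlm),
    data.frame(class = "GLSZM", feature = glszm),
    data.frame(class = "NGTDM", feature = ngtdm),
    data.frame(class = "IQ-wavelets", feature = iq))
  structure(cat_df, class = c("feature_catalog", "data.frame"))
}

#' Gray-level discretization and texture-matrix settings
#'
#' @param bin_width fixed intensity bin width for gray-level discretization
#'   (default 25 intensity units); mutually exclusive with `n_bins`.
#' @param n_bins fixed bin count alternative to `bin_width`.
#' @param distance neighbourhood distance (Chebyshev) for GLCM/NGTDM/GLDM.
#' @param gldm_alpha gray-level dependence cutoff: a neighbour is dependent
#'   when its discretized level differs by at most `gldm_alpha`.
#' @param wavelet wavelet family for the IQ features (`"haar"`).
#' @return an object of class `extraction_settings` carrying a settings id
#'   that is stamped into every feature vector.
#' @export
extraction_settings <- function(bin_width = 25, n_bins = NULL, distance = 1L,
                                gldm_alpha = 0, wavelet = "haar") {
  if (!is.null(n_bins)) {
    if (n_bins < 1) stop("n_bins must be positive", call. = FALSE)
  } else if (is.null(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive", call. = FALSE)
  }
  if (distance < 1) stop("distance must be >= 1", call. = FALSE)
  if (!identical(wavelet, "haar"))
    stop("only the haar wavelet is implemented", call. = FALSE)
  s <- list(bin_width = if (is.null(n_bins)) bin_width else NULL,
            n_bins = n_bins, distance = as.integer(distance),
            gldm_alpha = gldm_alpha, wavelet = wavelet)
  s$id <- config_id(s)
  structure(s, class = "extraction_settings")
}

# fixed-bin-width discretization: level 1 starts at min(v)
discretize_fbw <- function(v, bin_width) {
  floor((v - min(v)) / bin_width) + 1L
}

discretize_fbc <- function(v, n_bins) {
  rng <- max(v) - min(v)
  if (rng == 0) return(rep(1L, length(v)))
  lv <- floor((v - min(v)) / rng * n_bins) + 1L
  pmin(lv, n_bins)
}

discretize <- function(v, settings) {
  if (!is.null(settings$n_bins)) discretize_fbc(v, settings$n_bins)
  else discretize_fbw(v, settings$bin_width)
}
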