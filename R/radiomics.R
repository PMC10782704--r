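#' Discretization settings for texture features
#'
#' Fixed-bin-width intensity discretization relative to the masked minimum,
#' the convention under which untransformed-image ("original") features are
#' extracted. No resampling is applied before extraction by default.
#'
#' @param bin_width Bin width in HU (default 25).
#' @return An object of class `discretization_config`.
#' @export
discretization_config <- function(bin_width = 25) {
  stopifnot(bin_width > 0)
  structure(list(bin_width = bin_width), class = "discretization_config")
}

#' Discretize masked intensities into grey levels
#'
#' `level(v) = floor((v - min_masked) / width) + 1`; levels start at 1 and
#' shifting all intensities by a constant leaves the levels unchanged.
#'
#' @param volume An [image_volume()].
#' @param mask A nonempty [structure_mask()] on the same geometry.
#' @param cfg A [discretization_config()].
#' @return List: `levels` (integer array, 0 outside the mask), `n_levels`,
#'   `values` (the masked raw intensities), `bin_width`.
#' @export
discretize <- function(volume, mask, cfg = discretization_config()) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "structure_mask"))
  if (!geom_equal(volume$geometry, mask$geometry))
    stop("discretize: volume and mask geometries differ")
  inside <- mask$voxels == 1L
  if (!any(inside)) stop("discretize: empty mask")
  v <- volume$values[inside]
  lev <- array(0L, dim(volume$values))
  lev[inside] <- as.integer(floor((v - min(v)) / cfg$bin_width) + 1)
  list(levels = lev, n_levels = max(lev), values = v,
       bin_width = cfg$bin_width)
}

#' Names of the 107 original-image radiomic features
#'
#' 18 first-order, 14 3-D shape, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM and
#' 14 GLDM features; names are `family_Feature`.
#'
#' @return Data.frame with columns `feature`, `family`.
#' @export
feature_names <- function() {
  fam <- list(
    firstorder = c("Energy", "TotalEnergy", "Entropy", "Minimum",
                   "P10", "P90", "Maximum", "Mean", "Median",
                   "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                   "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                   "Skewness", "Kurtosis", "Variance", "Uniformity"),
    shape = c("MeshVolume", "VoxelVolume", "SurfaceArea",
              "SurfaceVolumeRatio", "Sphericity", "Maximum3DDiameter",
              "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
              "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength",
              "LeastAxisLength", "Elongation", "Flatness"),
    glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
             "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
             "JointAverage", "JointEnergy", "JointEntropy", "MCC",
             "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"),
    glrlm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "GrayLevelVariance", "HighGrayLevelRunEmphasis",
              "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
              "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
              "RunEntropy", "RunLengthNonUniformity",
              "RunLengthNonUniformityNormalized", "RunPercentage",
              "RunVariance", "ShortRunEmphasis",
              "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis"),
    glszm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
              "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
              "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
              "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
              "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
              "ZonePercentage", "ZoneVariance"),
    ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength"),
    gldm = c("DependenceEntropy", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "DependenceVariance",
             "GrayLevelNonUniformity", "GrayLevelVariance",
             "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
             "LargeDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
             "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
             "SmallDependenceLowGrayLevelEmphasis"))
  do.call(rbind, lapply(names(fam), function(f) {
    data.frame(feature = paste(f, fam[[f]], sep = "_"), family = f,
               stringsAsFactors = FALSE)
  }))
}

#' Extract the 107 original-image radiomic features
#'
#' First-order statistics on the raw masked intensities (histogram-based
#' entropy/uniformity use the discretized levels), 3-D shape features from
#' the voxelised mask, and five texture families (GLCM, GLRLM, GLSZM, NGTDM,
#' GLDM) on the discretized grid. Texture matrices use the 13 unique 3-D
#' directions at distance 1, symmetric accumulation, with per-direction
#' features averaged (GLCM, GLRLM). Degenerate features (single grey level,
#' single voxel, or otherwise undefined values) are returned as NA with
#' `degenerate = TRUE`, never silently dropped.
#'
#' @param volume An [image_volume()].
#' @param mask A nonempty [structure_mask()] on the same geometry.
#' @param cfg A [discretization_config()].
#' @return Data.frame of class `feature_vector`: `feature`, `family`,
#'   `value`, `degenerate`; exactly 107 rows.
#' @export
extract_features <- function(volume, mask, cfg = discretization_config()) {
  dz <- discretize(volume, mask, cfg)
  vals <- c(
    firstorder = firstorder_features(dz$values, voxel_volume_mm3(mask$geometry),
                                     dz),
    shape = shape_features(mask),
    glcm = glcm_features(dz),
    glrlm = glrlm_features(dz),
    glszm = glszm_features(dz),
    ngtdm = ngtdm_features(dz),
    gldm = gldm_features(dz))
  reg <- feature_names()
  # `c()` on named lists gives names like firstorder.Mean
  names(vals) <- sub("^([a-z]+)\\.", "\\1_", names(vals))
  stopifnot(setequal(names(vals), reg$feature))
  value <- unname(unlist(vals[reg$feature]))
  degenerate <- !is.finite(value)
  value[degenerate] <- NA_real_
  out <- data.frame(feature = reg$feature, family = reg$family, value = value,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  class(out) <- c("feature_vector", class(out))
  out
}

#' Paired CT-vs-pCT feature comparison with outlier handling
#'
#' Matches feature vectors case-by-case, removes features according to the
#' outlier rule, and tests the remainder with the paired Wilcoxon
#' signed-rank test. The default rule removes a feature when any case (in
#' either image set) produced a degenerate or non-finite value -- the
#' pattern seen when an organ is too small to support texture matrices. The
#' alternative `"iqr"` rule additionally screens values outside
#' median +/- `k` IQR across cases.
#'
#' @param a,b Lists of `feature_vector`s (same length, matched cases), e.g.
#'   planning-CT vs pseudo-CT.
#' @param outlier_rule `"degenerate"` or `"iqr"`.
#' @param k IQR multiplier for the `"iqr"` rule (default 3).
#' @return List: `table` (feature, family, removed, p, statistic, n) and
#'   `removed` (character vector of removed feature names).
#' @export
compare_features <- function(a, b, outlier_rule = c("degenerate", "iqr"),
                             k = 3) {
  outlier_rule <- match.arg(outlier_rule)
  if (length(a) != length(b) || length(a) == 0)
    stop("compare_features: unmatched case sets")
  reg <- feature_names()
  get_mat <- function(lst) {
    vapply(lst, function(fv) {
      stopifnot(inherits(fv, "feature_vector"))
      fv$value[match(reg$feature, fv$feature)]
    }, numeric(nrow(reg)))
  }
  A <- get_mat(a) # features x cases
  B <- get_mat(b)
  removed <- !is.finite(A) | !is.finite(B)
  removed_feat <- rowSums(removed) > 0
  if (outlier_rule == "iqr") {
    for (m in list(A, B)) {
      med <- apply(m, 1, stats::median, na.rm = TRUE)
      iqr <- apply(m, 1, stats::IQR, na.rm = TRUE)
      out <- abs(m - med) > k * pmax(iqr, .Machine$double.eps)
      removed_feat <- removed_feat | (rowSums(out, na.rm = TRUE) > 0 & iqr > 0)
    }
  }
  p <- stat <- rep(NA_real_, nrow(reg))
  for (i in which(!removed_feat)) {
    w <- wilcoxon_signed_rank(paired_sample(A[i, ], B[i, ]))
    p[i] <- w$p_value
    stat[i] <- w$statistic
  }
  tab <- data.frame(feature = reg$feature, family = reg$family,
                    removed = removed_feat, p = p, statistic = stat,
                    n = length(a), stringsAsFactors = FALSE)
  list(table = tab, removed = reg$feature[removed_feat])
}
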