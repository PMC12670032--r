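# Canonical 107-feature manifest: 18 first-order, 14 shape, 24 GLCM,
# 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM.

FEATURE_MANIFEST <- list(
  firstorder = c(
    "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
    "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
    "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
    "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"),
  shape = c(
    "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
    "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
    "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxisLength",
    "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness"),
  glcm = c(
    "Autocorrelation", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
    "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
    "JointEntropy", "MCC", "MaximumProbability", "SumAverage", "SumEntropy",
    "SumSquares"),
  glrlm = c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
    "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
    "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
    "ShortRunLowGrayLevelEmphasis"),
  glszm = c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
    "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
    "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
    "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
    "ZoneEntropy", "ZonePercentage", "ZoneVariance"),
  gldm = c(
    "DependenceEntropy", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "DependenceVariance",
    "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
    "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
    "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
    "SmallDependenceLowGrayLevelEmphasis"),
  ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
)

#' The canonical 107 radiomic feature names
#'
#' Names are `{class}_{feature}` in manifest order: 18 first-order, 14 shape,
#' 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM.
#'
#' @param classes Feature classes to include (default all seven).
#' @return Character vector (length 107 for all classes).
#' @export
feature_manifest <- function(classes = names(FEATURE_MANIFEST)) {
  unlist(lapply(classes, function(cl) paste0(cl, "_", FEATURE_MANIFEST[[cl]])),
         use.names = FALSE)
}

#' Write the feature manifest as JSON
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_manifest <- function(path) {
  jsonlite::write_json(FEATURE_MANIFEST, path, pretty = TRUE)
  invisible(path)
}
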