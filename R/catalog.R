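# The "original" feature set of a standard radiomics extraction: 107
# features across seven classes. shape_LeastAxisLength is flagged excluded
# because restricting segmentation to the middle portion of each object
# biases the least axis systematically; 106 features enter the analysis.

.feature_classes <- c("shape", "firstorder", "glcm", "glrlm", "glszm",
                      "gldm", "ngtdm")

.catalog_names <- list(
  shape = c(
    "Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
    "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
    "Maximum2DDiameterSlice", "Maximum3DDiameter", "MeshVolume",
    "MinorAxisLength", "Sphericity", "SurfaceArea", "SurfaceVolumeRatio",
    "VoxelVolume"
  ),
  firstorder = c(
    "10Percentile", "90Percentile", "Energy", "Entropy",
    "InterquartileRange", "Kurtosis", "Maximum", "Mean",
    "MeanAbsoluteDeviation", "Median", "Minimum", "Range",
    "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
    "TotalEnergy", "Uniformity", "Variance"
  ),
  glcm = c(
    "Autocorrelation", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
    "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
    "JointEntropy", "MCC", "MaximumProbability", "SumAverage",
    "SumEntropy", "SumSquares"
  ),
  glrlm = c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
    "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
    "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
    "ShortRunLowGrayLevelEmphasis"
  ),
  glszm = c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
    "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
    "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
    "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
    "ZoneEntropy", "ZonePercentage", "ZoneVariance"
  ),
  gldm = c(
    "DependenceEntropy", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "DependenceVariance",
    "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
    "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
    "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
    "SmallDependenceLowGrayLevelEmphasis"
  ),
  ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
)

#' Feature catalog of the standard "original" radiomic feature set
#'
#' Returns the fixed namespace of 107 radiomic features in seven classes
#' (shape, first order, GLCM, GLRLM, GLSZM, GLDM, NGTDM), as produced by a
#' default "original"-image extraction. One shape feature,
#' `shape_LeastAxisLength`, carries `excluded = TRUE`: segmentations
#' restricted to the middle portion of an object bias the least axis, so
#' 106 features form the analysis set.
#'
#' @return A tibble with columns `feature_name` (unique,
#'   `"<class>_<ShortName>"`), `feature_class` (factor over the seven
#'   classes), `short_name`, and `excluded` (logical).
#' @examples
#' cat <- build_feature_catalog()
#' nrow(cat)            # 107
#' sum(!cat$excluded)   # 106
#' @export
build_feature_catalog <- function() {
  cls <- rep(names(.catalog_names), lengths(.catalog_names))
  short <- unlist(.catalog_names, use.names = FALSE)
  tibble::tibble(
    feature_name = paste(cls, short, sep = "_"),
    feature_class = factor(cls, levels = .feature_classes),
    short_name = short,
    excluded = paste(cls, short, sep = "_") == "shape_LeastAxisLength"
  )
}

#' Split a feature name into class and short name
#'
#' Feature names follow the `"<class>_<ShortName>"` convention, e.g.
#' `"glcm_JointEntropy"`. The class token is lower-cased and must be one of
#' the seven known classes.
#'
#' @param name Character vector of feature names.
#' @return A tibble with columns `feature_class` and `short_name`.
#' @examples
#' parse_feature_name("ngtdm_Busyness")
#' @export
parse_feature_name <- function(name) {
  stopifnot(is.character(name), length(name) >= 1L)
  if (!all(grepl("_", name, fixed = TRUE))) {
    bad <- name[!grepl("_", name, fixed = TRUE)]
    stop("feature name without '<class>_<ShortName>' underscore: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cls <- tolower(sub("_.*$", "", name))
  unknown <- setdiff(unique(cls), .feature_classes)
  if (length(unknown) > 0L) {
    stop("unknown feature class prefix: ", paste(unknown, collapse = ", "),
         " (known: ", paste(.feature_classes, collapse = ", "), ")",
         call. = FALSE)
  }
  tibble::tibble(
    feature_class = factor(cls, levels = .feature_classes),
    short_name = sub("^[^_]*_", "", name)
  )
}
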