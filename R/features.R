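#' First-order intensity features (13 features)
#'
#' Computed on the raw (undiscretized) ROI intensities, except the histogram
#' entropy which uses the fixed-bin-number discretization. Variance and
#' standard deviation use the population (1/n) convention; skewness is the
#' standardized third moment and kurtosis the excess (standardized fourth
#' moment minus 3); both are 0 by convention for a constant ROI. Percentiles
#' use the default (type 7) quantile definition.
#'
#' @param image 3D numeric array.
#' @param mask binary 3D array, non-empty.
#' @param n_bins gray levels for the histogram entropy (default 32).
#' @return named numeric vector of length 13.
#' @export
intensity_features <- function(image, mask, n_bins = 32L) {
  d <- discretize(image, mask, n_bins)
  x <- d$values
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 - 3 else 0
  lev <- d$levels[!is.na(d$levels)]
  p <- tabulate(lev, nbins = d$n_g) / n
  ent <- -sum(p[p > 0] * log2(p[p > 0]))
  c(Mean = m,
    Median = median(x),
    Minimum = min(x),
    Maximum = max(x),
    Range = diff(range(x)),
    Variance = m2,
    StandardDeviation = sqrt(m2),
    Skewness = skew,
    Kurtosis = kurt,
    Energy = sum(x^2),
    Entropy = ent,
    P10 = unname(quantile(x, 0.10)),
    P90 = unname(quantile(x, 0.90)))
}

#' @keywords internal
FEATURE_FAMILIES <- function() {
  list(Intensity = c("Mean", "Median", "Minimum", "Maximum", "Range",
                     "Variance", "StandardDeviation", "Skewness", "Kurtosis",
                     "Energy", "Entropy", "P10", "P90"),
       GLCM = c("JointMaximum", "JointAverage", "JointVariance", "Entropy",
                "Energy", "Contrast", "Dissimilarity", "InverseDifference",
                "InverseDifferenceNorm", "InverseDifferenceMoment",
                "InverseDifferenceMomentNorm", "InverseVariance",
                "Correlation", "Autocorrelation", "ClusterTendency",
                "ClusterShade", "ClusterProminence", "SumAverage",
                "SumVariance", "SumEntropy", "DifferenceAverage",
                "DifferenceVariance", "DifferenceEntropy", "IMC1", "IMC2",
                "MCC"),
       GLRLM = c("SRE", "LRE", "GLN", "GLNN", "RLN", "RLNN", "RP", "GLV",
                 "RLV", "RE", "LGLRE", "HGLRE", "SRLGLE", "SRHGLE", "LRLGLE",
                 "LRHGLE", "GLA", "RLA"),
       GLSZM = c("SAE", "LAE", "GLN", "GLNN", "SZN", "SZNN", "ZP", "GLV",
                 "ZV", "ZE", "LGLZE", "HGLZE", "SALGLE", "SAHGLE", "LALGLE",
                 "LAHGLE", "GLA", "ZSA"))
}

#' Names of the fixed 101-feature roster
#'
#' 13 intensity features plus 88 textural features: the 26-feature GLCM
#' roster at offset distances 1 and 2 (52), 18 GLRLM features and 18 GLSZM
#' features. Names are prefixed with the modality, e.g.
#' \code{"ALFF_GLCM_Correlation"} or \code{"T1-w_GLRLM_RLN"}; the distance-2
#' GLCM block carries a \code{"_d2"} suffix.
#'
#' @param modality prefix string (\code{"T1-w"}, \code{"ALFF"}, ...).
#' @return character vector of length 101.
#' @export
feature_names <- function(modality = "T1-w") {
  fam <- FEATURE_FAMILIES()
  c(paste0(modality, "_Intensity_", fam$Intensity),
    paste0(modality, "_GLCM_", fam$GLCM),
    paste0(modality, "_GLCM_", fam$GLCM, "_d2"),
    paste0(modality, "_GLRLM_", fam$GLRLM),
    paste0(modality, "_GLSZM_", fam$GLSZM))
}

#' Extract the full 101-feature vector for one image/ROI
#'
#' Concatenates the 13 intensity features with the 88 textural features
#' (GLCM at distances 1 and 2 aggregated over the 13 unique directions of the
#' 26-neighbourhood, GLRLM, GLSZM), all computed on the fixed-bin-number
#' discretization with \code{n_bins} gray levels. Deterministic: identical
#' image and mask give an identical vector.
#'
#' @param image 3D numeric array (structural volume or ALFF map).
#' @param mask binary 3D array, non-empty.
#' @param n_bins gray levels for discretization (default 32).
#' @param modality name prefix (default \code{"T1-w"}).
#' @return named numeric vector of length 101.
#' @export
extract_feature_vector <- function(image, mask, n_bins = 32L,
                                   modality = "T1-w") {
  d <- discretize(image, mask, n_bins)
  out <- c(intensity_features(image, mask, n_bins),
           glcm_features(d, distance = 1L),
           glcm_features(d, distance = 2L),
           glrlm_features(d),
           glszm_features(d))
  names(out) <- feature_names(modality)
  if (any(!is.finite(out)))
    stop_data("non-finite feature value produced")
  out
}

#' Feature table for a set of subjects
#'
#' Applies \code{\link{extract_feature_vector}} to a named list of images
#' sharing one mask, returning a subjects x features data frame
#' (a FeatureTable) with subject ids as row names.
#'
#' @param images named list of 3D arrays (names = subject ids).
#' @param mask binary 3D array.
#' @param n_bins gray levels.
#' @param modality name prefix.
#' @return data frame, one row per subject, 101 columns.
#' @export
feature_table <- function(images, mask, n_bins = 32L, modality = "T1-w") {
  stopifnot(length(images) > 0)
  rows <- lapply(images, extract_feature_vector, mask = mask,
                 n_bins = n_bins, modality = modality)
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  rownames(tab) <- names(images) %||% sprintf("subject-%03d",
                                              seq_along(images))
  tab
}
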