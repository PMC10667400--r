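#' Names of the 107 features, by group
#'
#' Group cardinalities: FO 18, GLCM 24, GLDM 14, GLRLM 16, GLSZM 16, NGTDM 5,
#' Shape 14.
#'
#' @return Named character vector of length 107; names are the group labels.
#' @export
feature_names <- function() {
  fo <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
          "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
          "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
          "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")
  glcm <- c("Autocorrelation", "JointAverage", "ClusterProminence",
            "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
            "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
            "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn",
            "Id", "Idn", "InverseVariance", "MaximumProbability",
            "SumAverage", "SumEntropy", "SumSquares", "MCC")
  gldm <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
            "GrayLevelNonUniformity", "DependenceNonUniformity",
            "DependenceNonUniformityNormalized", "GrayLevelVariance",
            "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
            "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
            "SmallDependenceHighGrayLevelEmphasis",
            "LargeDependenceLowGrayLevelEmphasis",
            "LargeDependenceHighGrayLevelEmphasis")
  glrlm <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
             "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
             "RunLengthNonUniformityNormalized", "RunPercentage",
             "GrayLevelVariance", "RunVariance", "RunEntropy",
             "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
             "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
             "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  glszm <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
             "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
             "SizeZoneNonUniformityNormalized", "ZonePercentage",
             "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
             "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
             "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
             "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  ngtdm <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  shape <- c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
             "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
             "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
             "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
             "Elongation", "Flatness")
  out <- c(paste0("FO_", fo), paste0("GLCM_", glcm), paste0("GLDM_", gldm),
           paste0("GLRLM_", glrlm), paste0("GLSZM_", glszm),
           paste0("NGTDM_", ngtdm), paste0("Shape_", shape))
  names(out) <- rep(c("FO", "GLCM", "GLDM", "GLRLM", "GLSZM", "NGTDM", "Shape"),
                    times = c(18, 24, 14, 16, 16, 5, 14))
  out
}

#' Extract all 107 features for one scan of a lesion under one setting
#'
#' Runs [apply_setting()] and computes the first-order, texture, and shape
#' features. Shape features depend only on the final mask, so settings that
#' share an outlier mode give identical shape values.
#'
#' @param case A `paired_lesion_case`.
#' @param scan 1 or 2.
#' @param setting One-row setting data.frame.
#' @param anchors Normalization anchors (muscle, fat targets).
#' @param shape_cache Optional environment used to memoize shape features
#'   across settings that share a final mask.
#' @return Named numeric vector of 107 finite values.
#' @export
extract_all <- function(case, scan, setting, anchors = c(0, 1000),
                        shape_cache = NULL) {
  prep <- apply_setting(case, scan, setting, anchors = anchors)
  mats <- build_matrices(prep$disc)
  fo <- first_order_features(prep$volume, prep$mask, prep$disc, prep$spacing)
  tex <- texture_features(mats)
  key <- paste0("s", scan, "_", digest_mask(prep$mask))
  shp <- if (!is.null(shape_cache)) shape_cache[[key]] else NULL
  if (is.null(shp)) {
    shp <- shape_features(prep$mask, prep$spacing)
    if (!is.null(shape_cache)) shape_cache[[key]] <- shp
  }
  out <- c(fo, tex, shp)[feature_names()]
  stopifnot(length(out) == 107L, !anyNA(out))
  out
}

# cheap stable key for a logical array
digest_mask <- function(mask) {
  idx <- which(mask)
  paste0(length(idx), "_", sum(as.numeric(idx)), "_",
         sum(as.numeric(idx)^2) %% 1e15)
}

#' Extract the full feature table for a cohort
#'
#' Long-format table over lesion x scan x setting x feature. Cells whose ROI
#' becomes empty under OUT filtering are skipped with a warning and recorded
#' in the \code{failures} attribute rather than silently dropped.
#'
#' @param cohort List of `paired_lesion_case` (see [generate_cohort()]).
#' @param settings Setting grid (default [enumerate_settings()]).
#' @param anchors Normalization anchors.
#' @param verbose Print progress every few lesions.
#' @return data.frame with columns lesion_id, scan, setting_index,
#'   feature_name, value.
#' @export
extract_cohort <- function(cohort, settings = enumerate_settings(),
                           anchors = c(0, 1000), verbose = FALSE) {
  fnames <- feature_names()
  rows <- vector("list", length(cohort) * 2L * nrow(settings))
  failures <- list()
  k <- 0L
  for (ci in seq_along(cohort)) {
    case <- cohort[[ci]]
    for (scan in 1:2) {
      shape_cache <- new.env(parent = emptyenv())
      for (si in seq_len(nrow(settings))) {
        setting <- settings[si, , drop = FALSE]
        k <- k + 1L
        vals <- tryCatch(
          extract_all(case, scan, setting, anchors = anchors,
                      shape_cache = shape_cache),
          error = function(e) e)
        if (inherits(vals, "error")) {
          failures[[length(failures) + 1L]] <- list(
            lesion_id = case$lesion_id, scan = scan,
            setting_index = setting$setting_index,
            message = conditionMessage(vals))
          next
        }
        rows[[k]] <- data.frame(
          lesion_id = case$lesion_id, scan = scan,
          setting_index = setting$setting_index,
          feature_name = fnames, value = unname(vals),
          stringsAsFactors = FALSE)
      }
    }
    if (verbose && ci %% 5 == 0)
      message("extracted lesion ", ci, "/", length(cohort))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  if (length(failures))
    warning(length(failures), " (lesion, scan, setting) cells failed; see ",
            "attr(, 'failures')")
  attr(out, "failures") <- failures
  out
}
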