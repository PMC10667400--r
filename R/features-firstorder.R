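#' First-order intensity statistics (18 features)
#'
#' Computed from the continuous post-filter intensities inside the final
#' mask, except Entropy and Uniformity which use the discretized gray-level
#' histogram. All population moments use the N denominator; percentiles use
#' linear interpolation (type 7). TotalEnergy scales Energy by the voxel
#' volume in mm^3. Kurtosis is the raw fourth standardized moment (a normal
#' distribution gives 3, not 0).
#'
#' @param volume 3D numeric array (post-filter continuous intensities).
#' @param mask Logical array, final ROI mask.
#' @param disc A `discretized_roi` on the same ROI (for Entropy/Uniformity).
#' @param spacing Voxel spacing in mm, length 3.
#' @return Named numeric vector of 18 values, names prefixed "FO_".
#' @export
first_order_features <- function(volume, mask, disc, spacing) {
  x <- volume[mask]
  n <- length(x)
  vv <- prod(spacing)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  inner <- x[x >= q[1] & x <= q[4]]
  p <- tabulate(disc$levels[disc$mask], nbins = disc$ng)
  p <- p[p > 0] / sum(p)
  out <- c(
    Energy = sum(x^2),
    TotalEnergy = vv * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(x),
    Mean = mu,
    Median = stats::median(x),
    InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
  names(out) <- paste0("FO_", names(out))
  out
}
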