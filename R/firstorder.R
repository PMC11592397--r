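#' First-order intensity statistics
#'
#' The 18 standard first-order radiomics features. Histogram-based features
#' (Entropy, Uniformity) are computed on the discretized gray levels; the
#' remainder on the raw intensities. Entropy is in bits.
#'
#' @param values numeric vector of raw intensities inside the VOI.
#' @param levels integer gray levels of the same voxels (from
#'   [discretize_suv()]); if `NULL`, `values` are used directly as levels.
#' @param voxel_volume_mm3 single-voxel volume, used by TotalEnergy.
#' @return named numeric vector of 18 features.
#' @export
firstorder_features <- function(values, levels = NULL, voxel_volume_mm3 = 1) {
  stopifnot(length(values) > 0, all(is.finite(values)))
  if (is.null(levels)) levels <- as.integer(round(values))
  n <- length(values)
  mu <- mean(values)
  vr <- mean((values - mu)^2)            # population variance
  sdv <- sqrt(vr)
  p <- tabulate(levels - min(levels) + 1L)
  p <- p[p > 0] / n
  q <- stats::quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  rob <- values[values >= q[1] & values <= q[5]]
  c(
    Mean = mu,
    Variance = vr,
    Skewness = if (sdv > 0) mean((values - mu)^3) / sdv^3 else 0,
    Kurtosis = if (sdv > 0) mean((values - mu)^4) / sdv^4 else 0,
    Entropy = -sum(p * log2(p)),
    Uniformity = sum(p^2),
    Energy = sum(values^2),
    TotalEnergy = voxel_volume_mm3 * sum(values^2),
    Minimum = min(values),
    Maximum = max(values),
    Range = max(values) - min(values),
    Percentile10 = q[1],
    Percentile90 = q[5],
    InterquartileRange = q[4] - q[2],
    Median = q[3],
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(rob)) mean(abs(rob - mean(rob))) else 0,
    RootMeanSquared = sqrt(mean(values^2))
  )
}
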