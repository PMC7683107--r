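#' First-order intensity statistics
#'
#' The 18 standard first-order radiomic features of the ROI intensity
#' distribution.  `Entropy` and `Uniformity` are computed on the
#' discretized histogram (see [discretize()]); percentiles use linear
#' interpolation; `Skewness` and `Kurtosis` are population moments
#' (`Kurtosis` is not excess-corrected) and return 0 on constant ROIs,
#' where they are undefined.
#'
#' @param slice [image_slice()] or matrix.
#' @param mask logical ROI mask with at least one pixel.
#' @param discretization list of arguments passed to [discretize()].
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(slice, mask,
                                 discretization = list()) {
  slice <- as_slice(slice)
  mask <- roi_mask(mask)
  v <- slice$values[mask]
  n <- length(v)
  d <- do.call(discretize, c(list(slice = slice, mask = mask),
                             discretization))
  p <- tabulate(d$levels[mask], nbins = d$ng) / n
  p <- p[p > 0]
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  q <- quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  robust <- v[v >= q[1] & v <= q[5]]
  c(Energy = sum(v^2),
    TotalEnergy = prod(slice$spacing) * sum(v^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(v),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(v),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((v - mu)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}
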