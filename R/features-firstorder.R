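# First-order (intensity histogram) features. Entropy and Uniformity use
# the fixed-bin-width discretisation shared with the texture families;
# percentiles use the linear-interpolation quantile definition.

#' First-order intensity features of a VOI
#'
#' The 18 standardised first-order descriptors of the in-mask intensity
#' distribution. `Energy` is the sum of squared intensities and
#' `TotalEnergy` its product with the voxel volume (mm^3); `Entropy` and
#' `Uniformity` are computed on the fixed-bin-width histogram.
#'
#' @param vol An [image_volume()].
#' @param mask A [voi_mask()] on the same grid.
#' @param disc Discretisation from [discretise()] (computed if missing).
#' @param bin_width Bin width used when `disc` is missing.
#' @return Named numeric vector of 18 features.
#' @export
firstorder_features <- function(vol, mask, disc = NULL, bin_width = NULL) {
  check_same_grid(vol, mask)
  x <- vol$data[mask$data != 0L]
  if (length(x) == 0) stop("mask is empty", call. = FALSE)
  if (is.null(disc)) {
    if (is.null(bin_width)) stop("need `disc` or `bin_width`", call. = FALSE)
    disc <- discretise(vol, mask, bin_width)
  }
  lev <- disc$levels[mask$data != 0L]
  p <- tabulate(lev, disc$n_levels)
  p <- p / sum(p)
  pp <- p[p > 0]

  n <- length(x)
  mu <- mean(x)
  qs <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  mid <- x[x >= qs[1] & x <= qs[5]]

  c(
    Energy = sum(x^2),
    TotalEnergy = voxel_volume(vol) * sum(x^2),
    Entropy = -sum(pp * log2(pp)),
    Minimum = min(x),
    `10Percentile` = qs[1],
    `90Percentile` = qs[5],
    Maximum = max(x),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(mid - mean(mid))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(pp^2)
  )
}
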