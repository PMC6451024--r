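#' First-order (histogram) features of a masked region
#'
#' Seventeen intensity-statistics: mean, median, minimum, maximum, range,
#' variance (sample), standard deviation, skewness, kurtosis (Pearson,
#' non-excess), energy (sum of squared intensities), root mean square, mean
#' absolute deviation, 10th/90th percentiles, interquartile range, entropy
#' and uniformity. Entropy (base-2) and uniformity are computed on the
#' equal-width quantization histogram (`n_bins` bins over the within-mask
#' min-max range), so a constant region has entropy 0 and uniformity 1.
#'
#' @param values 3D numeric array (or a `volume_image`).
#' @param mask logical array (or `tumor_mask`) on the same grid.
#' @param n_bins histogram bins for entropy/uniformity (default 32).
#' @return named numeric vector of length 17.
#' @export
first_order_features <- function(values, mask, n_bins = 32) {
  if (inherits(values, "volume_image")) values <- values$values
  if (inherits(mask, "tumor_mask")) mask <- mask$values
  v <- values[mask]
  n <- length(v)
  if (n == 0) stop("empty mask")
  m <- mean(v)
  m2 <- mean((v - m)^2) # population moments for shape statistics
  qs <- unname(quantile(v, c(0.1, 0.25, 0.75, 0.9)))
  lev <- gray_level_quantize(array(values, dim = dim(values)),
                             array(mask, dim = dim(mask)), n_bins)
  pbin <- tabulate(lev$values[mask], nbins = n_bins) / n
  pb <- pbin[pbin > 0]
  stats::setNames(
    c(m, median(v), min(v), max(v), max(v) - min(v),
      if (n > 1) var(v) else 0, if (n > 1) sd(v) else 0,
      if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0,
      if (m2 > 0) mean((v - m)^4) / m2^2 else 0,
      sum(v^2), sqrt(mean(v^2)), mean(abs(v - m)),
      qs[1], qs[4], qs[3] - qs[2],
      -sum(pb * log2(pb)), sum(pbin^2)),
    first_order_names())
}

first_order_names <- function() {
  c("mean", "median", "minimum", "maximum", "range", "variance", "sd",
    "skewness", "kurtosis", "energy", "rms", "mad", "p10", "p90", "iqr",
    "entropy", "uniformity")
}
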