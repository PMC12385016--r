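## First-order intensity statistics over the masked region.

#' First-order radiomic features
#'
#' Eighteen intensity statistics of the raw in-mask values. Moment-based
#' features (variance, skewness, kurtosis) use the population convention
#' (divide by n); kurtosis is non-excess (a Gaussian scores 3). Entropy and
#' uniformity are computed over the discretized level histogram. Percentiles
#' use linear interpolation. Degenerate conventions: a constant ROI has
#' variance 0, skewness 0, kurtosis 0, entropy 0 and uniformity 1.
#'
#' @param roi a [discretize()]d ROI.
#' @return Named numeric vector of 18 features (prefix `fo_`).
#' @export
first_order <- function(roi) {
  x <- roi$values
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  in_robust <- x >= q[1] & x <= q[4]
  p_lev <- tabulate(roi$levels[roi$mask], nbins = roi$n_levels) / n
  p_pos <- p_lev[p_lev > 0]
  c(fo_energy = sum(x^2),
    fo_total_energy = sum(x^2),          # unit pixel spacing; scaled by caller if needed
    fo_entropy = -sum(p_pos * log2(p_pos)),
    fo_minimum = min(x),
    fo_p10 = q[1],
    fo_p90 = q[4],
    fo_maximum = max(x),
    fo_mean = mu,
    fo_median = stats::median(x),
    fo_iqr = q[3] - q[2],
    fo_range = max(x) - min(x),
    fo_mad = mean(abs(x - mu)),
    fo_rmad = if (any(in_robust)) mean(abs(x[in_robust] - mean(x[in_robust]))) else 0,
    fo_rms = sqrt(mean(x^2)),
    fo_skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    fo_kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    fo_variance = m2,
    fo_uniformity = sum(p_lev^2))
}
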