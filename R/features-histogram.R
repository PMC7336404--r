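#' Histogram (first-order intensity) features
#'
#' Thirteen distribution features of the z-scored intensities inside the
#' tumour mask: mean, skewness, excess kurtosis (Fisher), sample standard
#' deviation, minimum, maximum and the 1st, 5th, 25th, 50th, 75th, 95th and
#' 99th percentiles. Skewness and kurtosis follow the moment (type 1)
#' definitions g1 = m3/m2^(3/2) and g2 = m4/m2^2 - 3; both are defined as 0
#' for zero-variance input. Percentiles interpolate linearly between order
#' statistics (R quantile type 7).
#'
#' @param z_values Numeric vector of masked voxel values (length >= 1).
#' @return Named numeric vector of the 13 features.
#' @export
histogram_features <- function(z_values) {
  z_values <- as.numeric(z_values)
  if (length(z_values) == 0L) stop("histogram_features: empty input")
  if (any(!is.finite(z_values))) stop("histogram_features: non-finite values")
  s <- stats::sd(z_values)
  if (length(z_values) == 1L) s <- 0
  degenerate <- !is.finite(s) || s == 0
  skew <- if (degenerate) 0 else e1071::skewness(z_values, type = 1)
  kurt <- if (degenerate) 0 else e1071::kurtosis(z_values, type = 1)
  q <- stats::quantile(z_values, c(.01, .05, .25, .50, .75, .95, .99),
                       names = FALSE, type = 7)
  c(mean = mean(z_values),
    skewness = skew,
    kurtosis = kurt,
    std = if (degenerate) 0 else s,
    min = min(z_values),
    max = max(z_values),
    p1 = q[1], p5 = q[2], p25 = q[3], p50 = q[4],
    p75 = q[5], p95 = q[6], p99 = q[7])
}
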