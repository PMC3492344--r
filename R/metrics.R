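as_values <- function(sample) {
  if (inherits(sample, "pixel_sample")) sample$values else as.numeric(sample)
}

#' Mean of the brightest fraction of a pixel sample
#'
#' Returns the mean of the `k` largest values, where
#' `k = max(1, ceiling(fraction * n))`: the top set is never empty and the
#' rounding rule is deterministic. Ties among equal values are immaterial.
#'
#' @param sample a `pixel_sample` or numeric vector.
#' @param fraction fraction of pixels to average, in (0, 1].
#' @return the top-fraction mean.
#' @export
top_fraction_mean <- function(sample, fraction = 0.05) {
  v <- as_values(sample)
  if (!length(v)) stop("empty pixel sample", call. = FALSE)
  stopifnot(fraction > 0, fraction <= 1)
  k <- max(1L, ceiling(fraction * length(v)))
  mean(sort(v, decreasing = TRUE)[seq_len(k)])
}

#' Biased sample skewness of a pixel sample
#'
#' The third standardized moment with divisor-n central moments,
#' `s = m3 / m2^(3/2)`. A fly with a compact bright thoracic spot over a
#' dimmer body yields a long right tail, hence high skewness; diffuse
#' autofluorescence yields a more symmetric distribution.
#'
#' @param sample a `pixel_sample` or numeric vector with at least 3 values
#'   and non-zero variance.
#' @return the skewness (dimensionless).
#' @export
skewness <- function(sample) {
  v <- as_values(sample)
  n <- length(v)
  if (n < 3) stop("skewness needs at least 3 values", call. = FALSE)
  mu <- mean(v)
  d <- v - mu
  m2 <- mean(d^2)
  if (m2 <= 0) stop("degenerate sample: zero variance", call. = FALSE)
  mean(d^3) / m2^1.5
}

ratio_of_image_means <- function(front_samples, rear_samples, stat, label) {
  if (inherits(front_samples, "pixel_sample")) front_samples <- list(front_samples)
  if (inherits(rear_samples, "pixel_sample")) rear_samples <- list(rear_samples)
  if (length(front_samples) != length(rear_samples) || !length(front_samples)) {
    stop("front and rear sample lists must be non-empty and frame-aligned",
         call. = FALSE)
  }
  num <- mean(vapply(front_samples, stat, numeric(1)))
  den <- mean(vapply(rear_samples, stat, numeric(1)))
  if (den == 0) {
    src <- if (inherits(rear_samples[[1]], "pixel_sample"))
      rear_samples[[1]]$source$fly_id
    stop(sprintf("%s: time-averaged rear value is zero (fly_id=%s)", label,
                 if (is.null(src)) "?" else src), call. = FALSE)
  }
  num / den
}

#' Max 5% Ratio metric
#'
#' The time-averaged mean of the brightest 5% of Front-ROI pixels divided by
#' the time-averaged mean of the brightest 5% of Rear-ROI pixels. Numerator
#' and denominator are each averaged over images *before* dividing
#' (ratio-of-averages mode). The ratiometric form cancels uniform changes in
#' excitation intensity, making the metric dimensionless.
#'
#' @param front_samples,rear_samples frame-aligned lists of `pixel_sample`s
#'   (or single samples) from the Front and Rear ROI of one fly.
#' @param fraction brightest fraction to average per image (default 0.05).
#' @return the ratio (dimensionless).
#' @export
max5_ratio <- function(front_samples, rear_samples, fraction = 0.05) {
  ratio_of_image_means(front_samples, rear_samples,
                       function(s) top_fraction_mean(s, fraction),
                       "max5_ratio")
}

#' Single-maximum ratio metric
#'
#' As [max5_ratio()] but using the single brightest pixel per ROI per image.
#' Performs like the 5% variant on clean data but is less robust to pixel
#' noise.
#'
#' @inheritParams max5_ratio
#' @return the ratio (dimensionless).
#' @export
single_max_ratio <- function(front_samples, rear_samples) {
  ratio_of_image_means(front_samples, rear_samples,
                       function(s) max(as_values(s)), "single_max_ratio")
}

#' Average a per-image metric across images
#'
#' Arithmetic mean, the averaging rule for metrics computed independently per
#' image (the Skewness metric); ratio metrics instead average numerator and
#' denominator separately, see [max5_ratio()].
#'
#' @param per_image_values numeric vector of per-image metric values.
#' @return their mean.
#' @export
average_metric_over_images <- function(per_image_values) {
  stopifnot(length(per_image_values) >= 1)
  mean(per_image_values)
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Min-max normalize a metric value against a calibration range
#' @param v metric value(s).
#' @param range numeric `c(lo, hi)` observed on the calibration cohort.
#' @param name metric name used in error messages.
#' @return value(s) clipped to `[0, 1]`.
#' @export
normalize_metric <- function(v, range, name = "metric") {
  lo <- range[1]; hi <- range[2]
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    stop(sprintf("degenerate normalization range for %s", name), call. = FALSE)
  }
  clip01((v - lo) / (hi - lo))
}

#' Weighted combination of two normalized metrics
#'
#' Each metric is min-max normalized to `[0, 1]` using ranges fixed from the
#' calibration cohort (and persisted with the calibration), then combined as
#' `w * n1 + (1 - w) * n2`. At `w = 0` or `w = 1` the combination reduces to
#' a single normalized metric.
#'
#' @param v1,v2 metric values (vectors of equal length).
#' @param w weight on metric 1, in `[0, 1]`.
#' @param norm1,norm2 normalization ranges `c(lo, hi)` for each metric.
#' @return combined score(s) in `[0, 1]`.
#' @export
combined_score <- function(v1, v2, w, norm1, norm2) {
  stopifnot(w >= 0, w <= 1)
  n1 <- normalize_metric(v1, norm1, "metric 1")
  n2 <- normalize_metric(v2, norm2, "metric 2")
  w * n1 + (1 - w) * n2
}
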