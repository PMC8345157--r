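# Feature registry: the canonical 212-feature dosiomics panel.

STAT_NAMES <- c(
  "mean", "variance", "skewness", "kurtosis", "median", "minimum",
  "percentile10", "percentile90", "maximum", "interquartile_range", "range",
  "mean_absolute_deviation", "robust_mean_absolute_deviation",
  "median_absolute_deviation", "coefficient_of_variation", "energy",
  "root_mean_square")

GLCM_NAMES <- c(
  "joint_maximum", "joint_average", "joint_variance", "joint_entropy",
  "difference_average", "difference_variance", "difference_entropy",
  "sum_average", "sum_variance", "sum_entropy", "angular_second_moment",
  "contrast", "dissimilarity", "inverse_difference",
  "inverse_difference_normalised", "inverse_difference_moment",
  "inverse_difference_moment_normalised", "inverse_variance", "correlation",
  "autocorrelation", "cluster_tendency", "cluster_shade",
  "cluster_prominence", "information_correlation_1",
  "information_correlation_2")

GLRLM_NAMES <- c(
  "short_run_emphasis", "long_run_emphasis", "low_grey_level_run_emphasis",
  "high_grey_level_run_emphasis", "short_run_low_grey_level_emphasis",
  "short_run_high_grey_level_emphasis", "long_run_low_grey_level_emphasis",
  "long_run_high_grey_level_emphasis", "grey_level_non_uniformity",
  "grey_level_non_uniformity_normalised", "run_length_non_uniformity",
  "run_length_non_uniformity_normalised", "run_percentage",
  "grey_level_variance", "run_length_variance", "run_entropy")

GLSZM_NAMES <- c(
  "small_zone_emphasis", "large_zone_emphasis", "low_grey_level_zone_emphasis",
  "high_grey_level_zone_emphasis", "small_zone_low_grey_level_emphasis",
  "small_zone_high_grey_level_emphasis", "large_zone_low_grey_level_emphasis",
  "large_zone_high_grey_level_emphasis", "grey_level_non_uniformity",
  "grey_level_non_uniformity_normalised", "zone_size_non_uniformity",
  "zone_size_non_uniformity_normalised", "zone_percentage",
  "grey_level_variance", "zone_size_variance", "zone_size_entropy")

GLCM_AGGS  <- c("2D_avg", "2D_merge", "3D_avg", "3D_merge")
GLRLM_AGGS <- GLCM_AGGS
GLSZM_AGGS <- c("2D_merge", "3D")

#' Default dosiomics feature registry
#'
#' The canonical panel: 17 intensity statistics (STAT, computed on raw dose
#' in Gy), 25 co-occurrence features under 4 aggregations (GLCM, 100),
#' 16 run-length features under 4 aggregations minus one configured entry
#' (GLRLM, 63), and 16 size-zone features under 2 aggregations (GLSZM, 32)
#' — 212 features in total. Texture families operate on the grey-level
#' discretisation.
#'
#' The run-length family counts 63 rather than 64 because one
#' (name, aggregation) entry is dropped from the panel; the default drops
#' `run_entropy` under the slice-averaged 2D aggregation. Any single entry
#' can be configured instead.
#'
#' @param glrlm_drop length-2 character vector `c(name, aggregation)` naming
#'   the run-length entry excluded from the panel.
#' @return A data frame of class `feature_registry` with columns `family`,
#'   `name`, `aggregation` and `feature_id`, 212 rows by default.
#' @export
default_registry <- function(glrlm_drop = c("run_entropy", "2D_avg")) {
  stat <- data.frame(family = "STAT", name = STAT_NAMES, aggregation = "none")
  glcm <- expand.grid(name = GLCM_NAMES, aggregation = GLCM_AGGS,
                      stringsAsFactors = FALSE)
  glcm$family <- "GLCM"
  glrlm <- expand.grid(name = GLRLM_NAMES, aggregation = GLRLM_AGGS,
                       stringsAsFactors = FALSE)
  glrlm$family <- "GLRLM"
  if (!is.null(glrlm_drop)) {
    if (length(glrlm_drop) != 2L || !glrlm_drop[1] %in% GLRLM_NAMES ||
        !glrlm_drop[2] %in% GLRLM_AGGS)
      stop("`glrlm_drop` must be c(<run-length feature name>, <aggregation>)")
    glrlm <- glrlm[!(glrlm$name == glrlm_drop[1] &
                       glrlm$aggregation == glrlm_drop[2]), ]
  }
  glszm <- expand.grid(name = GLSZM_NAMES, aggregation = GLSZM_AGGS,
                       stringsAsFactors = FALSE)
  glszm$family <- "GLSZM"
  reg <- rbind(stat[c("family", "name", "aggregation")],
               glcm[c("family", "name", "aggregation")],
               glrlm[c("family", "name", "aggregation")],
               glszm[c("family", "name", "aggregation")])
  reg$feature_id <- ifelse(reg$family == "STAT",
                           paste("STAT", reg$name, sep = "_"),
                           paste(reg$family, reg$name, reg$aggregation, sep = "_"))
  if (anyDuplicated(reg$feature_id)) stop("registry has duplicate feature ids")
  rownames(reg) <- NULL
  class(reg) <- c("feature_registry", "data.frame")
  reg
}

#' Per-family sizes of a registry
#' @param registry a [default_registry()]-style data frame.
#' @return Named integer vector with one count per family plus `total`.
#' @export
registry_counts <- function(registry = default_registry()) {
  tab <- table(factor(registry$family, levels = c("STAT", "GLCM", "GLRLM", "GLSZM")))
  c(as.vector(tab), total = nrow(registry)) |>
    stats::setNames(c(names(tab), "total"))
}

# The counts the default panel must satisfy.
EXPECTED_COUNTS <- c(STAT = 17L, GLCM = 100L, GLRLM = 63L, GLSZM = 32L, total = 212L)

#' Intensity-based statistics on raw ROI dose
#'
#' The 17 STAT features, computed on absolute dose in Gy with population
#' (biased, 1/n) moment conventions: mean, variance, skewness, excess
#' kurtosis, median, minimum, 10th/90th percentiles, maximum, interquartile
#' range, range, mean absolute deviation (about the mean), robust mean
#' absolute deviation (restricted to values within the 10th-90th percentile
#' band), median absolute deviation (mean absolute deviation about the
#' median), coefficient of variation, energy and root mean square. Skewness
#' and kurtosis of a constant input are undefined and returned as `NA`.
#'
#' @param values numeric vector of ROI voxel doses (>= 2 values).
#' @return Named numeric vector of length 17 (names `STAT_<name>`).
#' @export
stat_features <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  qs <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  p10 <- qs[1]; q1 <- qs[2]; med <- qs[3]; q3 <- qs[4]; p90 <- qs[5]
  rob <- values[values >= p10 & values <= p90]
  out <- c(
    mean = mu,
    variance = m2,
    skewness = if (m2 > 0) mean((values - mu)^3) / m2^1.5 else NA_real_,
    kurtosis = if (m2 > 0) mean((values - mu)^4) / m2^2 - 3 else NA_real_,
    median = med,
    minimum = min(values),
    percentile10 = p10,
    percentile90 = p90,
    maximum = max(values),
    interquartile_range = q3 - q1,
    range = max(values) - min(values),
    mean_absolute_deviation = mean(abs(values - mu)),
    robust_mean_absolute_deviation =
      if (length(rob)) mean(abs(rob - mean(rob))) else NA_real_,
    median_absolute_deviation = mean(abs(values - med)),
    coefficient_of_variation = if (mu != 0) sqrt(m2) / mu else NA_real_,
    energy = sum(values^2),
    root_mean_square = sqrt(mean(values^2))
  )
  stats::setNames(out, paste0("STAT_", STAT_NAMES))
}
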