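#' Count-weighted moments of an attenuation histogram
#'
#' Population (not sample-corrected) moments over the bin centers, weighted
#' by voxel counts. Kurtosis is the Pearson (non-excess) convention: a
#' Gaussian histogram gives 3.
#'
#' @param hist an `ssn_histogram`
#' @return named numeric vector `(mean, sd, skewness, kurtosis)`; sd is `NA`
#'   for a single-voxel histogram, and zero spread is an error because the
#'   standardized moments are undefined there
#' @export
histogram_moments <- function(hist) {
  n <- hist$total_voxels
  if (n < 1) stop("empty histogram")
  w <- hist$counts / n
  m <- sum(w * hist$bin_centers)
  if (n < 2) return(c(mean = m, sd = NA_real_, skewness = NA_real_,
                      kurtosis = NA_real_))
  d <- hist$bin_centers - m
  v <- sum(w * d^2)
  s <- sqrt(v)
  if (s == 0)
    stop("degenerate histogram: zero spread, skewness/kurtosis undefined")
  c(mean = m, sd = s,
    skewness = sum(w * d^3) / s^3,
    kurtosis = sum(w * d^4) / v^2)
}

#' Weighted quantiles of an attenuation histogram
#'
#' Treats the mass of each bin as uniformly spread inside the bin (linear
#' CDF inversion), so quantiles vary continuously and are non-decreasing in
#' the probability.
#'
#' @param hist an `ssn_histogram`
#' @param probs probabilities in (0, 1)
#' @return quantile values in HU, one per probability
#' @export
histogram_quantiles <- function(hist, probs) {
  if (hist$total_voxels < 1) stop("empty histogram")
  stopifnot(all(probs > 0), all(probs < 1))
  h <- diff(hist$bin_centers[1:2])
  edges <- c(hist$bin_centers - h / 2, hist$bin_centers[length(hist$bin_centers)] + h / 2)
  cdf <- c(0, cumsum(hist$counts)) / hist$total_voxels
  vapply(probs, function(p) {
    i <- findInterval(p, cdf, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(hist$counts))
    # skip empty bins the probability landed on the edge of
    while (hist$counts[i] == 0 && i < length(hist$counts)) i <- i + 1L
    edges[i] + (p - cdf[i]) / (cdf[i + 1] - cdf[i]) * h
  }, numeric(1))
}

#' Consolidation ratio of a part-solid nodule
#'
#' Maximum solid-component diameter divided by the maximum tumor diameter; 0
#' for a pure ground-glass nodule, 1 for a fully solid one.
#'
#' @param max_consolidation_mm,max_diameter_mm diameters in mm
#' @return ratio in \[0, 1\]
#' @export
consolidation_ratio <- function(max_consolidation_mm, max_diameter_mm) {
  if (any(max_diameter_mm <= 0)) stop("max diameter must be positive")
  if (any(max_consolidation_mm < 0)) stop("consolidation must be non-negative")
  if (any(max_consolidation_mm > max_diameter_mm))
    stop("consolidation cannot exceed the maximum diameter")
  max_consolidation_mm / max_diameter_mm
}

#' Geometric predictors of a nodule record
#'
#' @param record an `ssn_nodule`
#' @return named vector: `log10_volume` (volume in mm^3 on the log10 scale)
#'   and `diameter_ratio` (max/min diameter, an irregularity index >= 1)
#' @export
geometry_features <- function(record) {
  if (record$volume_mm3 <= 0 || record$min_diameter_mm <= 0)
    stop("volume and minimum diameter must be positive")
  c(log10_volume = log10(record$volume_mm3),
    diameter_ratio = record$max_diameter_mm / record$min_diameter_mm)
}

#' Assemble the per-nodule feature table
#'
#' One row per nodule with all a-priori features: histogram moments, the
#' upper quantiles Q.50/Q.75/Q.875 and the IQR, consolidation ratio,
#' log10 volume, diameters and the max/min diameter ratio, plus the class
#' label. Functional PC scores are joined later by [add_fpc_scores()].
#'
#' @param cohort an `ssn_cohort`
#' @return a data.frame with one row per nodule, in input order
#' @export
assemble_feature_table <- function(cohort) {
  ids <- vapply(cohort, function(r) r$nodule_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate nodule_id: ", ids[duplicated(ids)][1])
  rows <- lapply(cohort, function(r) {
    mom <- tryCatch(histogram_moments(r$histogram),
                    error = function(e) stop("nodule ", r$nodule_id, ": ",
                                             conditionMessage(e), call. = FALSE))
    q <- histogram_quantiles(r$histogram, c(0.25, 0.5, 0.75, 0.875))
    geo <- geometry_features(r)
    data.frame(
      nodule_id = r$nodule_id, class_label = r$class_label,
      pathology_subtype = r$pathology_subtype,
      mean_hu = mom[["mean"]], sd_hu = mom[["sd"]],
      skewness_hu = mom[["skewness"]], kurtosis_hu = mom[["kurtosis"]],
      q50_hu = q[2], q75_hu = q[3], q875_hu = q[4], iqr_hu = q[3] - q[1],
      consolidation_ratio = consolidation_ratio(r$max_consolidation_mm,
                                                r$max_diameter_mm),
      log10_volume = geo[["log10_volume"]],
      min_diameter_mm = r$min_diameter_mm,
      max_diameter_mm = r$max_diameter_mm,
      mean_diameter_mm = r$mean_diameter_mm,
      diameter_ratio = geo[["diameter_ratio"]]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature table to CSV at full double precision
#' @param feature_table data.frame from [assemble_feature_table()]
#' @param path output file
#' @export
write_feature_table <- function(feature_table, path) {
  write_csv_full(feature_table, path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV file
#' @return data.frame
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
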