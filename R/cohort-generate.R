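#' Bin centers of the attenuation histogram support
#' @param hist_cfg the `hist` element of a generator config (or a compatible
#'   list with `hu_min`, `hu_max`, `bin_width`)
#' @return numeric vector of uniformly spaced bin centers
#' @export
histogram_bin_centers <- function(hist_cfg) {
  seq(hist_cfg$hu_min, hist_cfg$hu_max, by = hist_cfg$bin_width)
}

new_histogram <- function(bin_centers, counts) {
  stopifnot(length(bin_centers) == length(counts), all(counts >= 0))
  structure(list(bin_centers = bin_centers, counts = as.integer(counts),
                 total_voxels = as.integer(sum(counts))),
            class = "ssn_histogram")
}

# Map attenuation values to bin indices and tabulate.
bin_values <- function(x, hist_cfg) {
  centers <- histogram_bin_centers(hist_cfg)
  idx <- round((x - hist_cfg$hu_min) / hist_cfg$bin_width) + 1
  idx <- clamp(idx, 1L, length(centers))
  new_histogram(centers, tabulate(idx, nbins = length(centers)))
}

#' Resolve the two-component attenuation mixture for one nodule
#'
#' Each nodule's histogram is a truncated two-component Gaussian mixture on
#' the HU support: a dominant ground-glass component and a higher-attenuation
#' (solid) component whose weight grows with the consolidation ratio. Given
#' the nodule's target histogram mean and SD, component locations are solved
#' so that the untruncated mixture reproduces the target mean and SD exactly.
#'
#' @param mean_hu,sd_hu target histogram mean and SD in HU
#' @param consol_ratio consolidation ratio in [0, 1]
#' @param hist_cfg histogram model settings (see [generator_config()])
#' @return list(w, m_gg, s_gg, m_s, s_s) with `w` the solid weight
#' @export
mixture_params <- function(mean_hu, sd_hu, consol_ratio, hist_cfg) {
  stopifnot(sd_hu > 0, consol_ratio >= 0, consol_ratio <= 1)
  w <- clamp(hist_cfg$solid_w0 + hist_cfg$solid_w1 * consol_ratio, 0.03, 0.45)
  s_gg <- hist_cfg$sgg_frac * sd_hu
  s_s <- hist_cfg$ss_frac * sd_hu
  # between-component variance needed to reach the target total variance
  B <- sd_hu^2 - (1 - w) * s_gg^2 - w * s_s^2
  sep <- if (B > 0) sqrt(B / ((1 - w) * w)) else 0
  m_gg <- mean_hu - w * sep
  m_s <- mean_hu + (1 - w) * sep
  a <- hist_cfg$hu_min; b <- hist_cfg$hu_max
  inside <- (1 - w) * (stats::pnorm(b, m_gg, s_gg) - stats::pnorm(a, m_gg, s_gg)) +
    w * (stats::pnorm(b, m_s, s_s) - stats::pnorm(a, m_s, s_s))
  if (inside < 0.5)
    stop("more than half of the mixture mass falls outside the HU support")
  list(w = w, m_gg = m_gg, s_gg = s_gg, m_s = m_s, s_s = s_s)
}

#' Sample one attenuation histogram
#'
#' Draws `n_voxels` attenuation values from the nodule's truncated Gaussian
#' mixture (see [mixture_params()]) and bins them on the configured support.
#' Uses the current RNG state; identical state gives identical counts.
#'
#' @inheritParams mixture_params
#' @param n_voxels number of voxels (positive integer)
#' @return an `ssn_histogram`: bin centers, integer counts, total voxel count
#' @export
sample_histogram <- function(mean_hu, sd_hu, consol_ratio, hist_cfg, n_voxels) {
  stopifnot(n_voxels >= 1)
  p <- mixture_params(mean_hu, sd_hu, consol_ratio, hist_cfg)
  solid <- stats::runif(n_voxels) < p$w
  x <- numeric(n_voxels)
  a <- hist_cfg$hu_min; b <- hist_cfg$hu_max
  n_s <- sum(solid)
  if (n_s > 0) x[solid] <- rtruncnorm(n_s, p$m_s, p$s_s, a, b)
  if (n_s < n_voxels) x[!solid] <- rtruncnorm(n_voxels - n_s, p$m_gg, p$s_gg, a, b)
  bin_values(x, hist_cfg)
}

# Draw the correlated base features for one class on the latent normal scale
# and map them through the calibrated marginals (Gaussian copula: the
# marginals are exact, the correlation is induced on the normal scores).
sample_base_features <- function(n, marg, copula) {
  L <- chol(copula + diag(1e-10, nrow(copula)))
  Z <- matrix(stats::rnorm(n * nrow(copula)), n) %*% L
  colnames(Z) <- latent_names
  U <- stats::pnorm(Z)
  data.frame(
    volume_mm3 = stats::qlnorm(U[, "volume"], marg$volume$meanlog, marg$volume$sdlog),
    mean_diameter_mm = stats::qlnorm(U[, "mean_diam"], marg$mean_diam$meanlog,
                                     marg$mean_diam$sdlog),
    diameter_ratio = 1 + stats::qlnorm(U[, "diam_ratio"], marg$diam_ratio$meanlog,
                                       marg$diam_ratio$sdlog),
    consol_ratio = stats::plogis(marg$consol$mu + marg$consol$sigma * Z[, "consol"]),
    mean_hu = clamp(marg$mean_hu$mean + marg$mean_hu$sd * Z[, "mean_hu"], -900, 150),
    sd_hu = clamp(stats::qlnorm(U[, "sd_hu"], marg$sd_hu$meanlog, marg$sd_hu$sdlog),
                  60, 320)
  )
}

make_record <- function(id, class_label, subtype, base, hist) {
  r <- base$diameter_ratio
  m <- base$mean_diameter_mm
  # min/max consistent with the sampled mean diameter and max/min ratio
  min_d <- 2 * m / (1 + r)
  max_d <- r * min_d
  structure(list(
    nodule_id = id, class_label = class_label, pathology_subtype = subtype,
    volume_mm3 = base$volume_mm3,
    min_diameter_mm = min_d, max_diameter_mm = max_d, mean_diameter_mm = m,
    max_consolidation_mm = base$consol_ratio * max_d,
    histogram = hist
  ), class = "ssn_nodule")
}

#' Generate a synthetic subsolid-nodule cohort
#'
#' Draws `n_T1 + n_T2` nodules whose per-class distributions of volume,
#' diameters, consolidation ratio and attenuation-histogram summaries are
#' calibrated to the published two-group cohort (56 pre-invasive/minimally
#' invasive vs 53 invasive nodules). Fully deterministic given `config$seed`.
#'
#' @param config an [generator_config()] object
#' @return an `ssn_cohort`: a list of `ssn_nodule` records with the config
#'   attached as attribute `config`
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  withr::with_seed(derive_seed(config$seed, "cohort"), {
    classes <- c(rep("T1", config$n_T1), rep("T2", config$n_T2))
    subtype_pool <- rep(names(config$t1_subtype_ratio),
                        times = config$t1_subtype_ratio)
    subtypes <- c(sample(subtype_pool, config$n_T1, replace = TRUE),
                  rep("IPA", config$n_T2))
    base_t1 <- sample_base_features(config$n_T1, config$marginals$T1, config$copula)
    base_t2 <- sample_base_features(config$n_T2, config$marginals$T2, config$copula)
    base <- rbind(base_t1, base_t2)
    records <- vector("list", nrow(base))
    for (i in seq_len(nrow(base))) {
      nv <- max(50L, as.integer(round(base$volume_mm3[i] /
                                        config$hist$voxel_volume_mm3)))
      hist <- sample_histogram(base$mean_hu[i], base$sd_hu[i],
                               base$consol_ratio[i], config$hist, nv)
      records[[i]] <- make_record(sprintf("SSN%03d", i), classes[i],
                                  subtypes[i], base[i, ], hist)
    }
    structure(records, class = "ssn_cohort", config = config)
  })
}

#' Perturb a cohort into a second-reader variant
#'
#' Emulates independent manual correction of nodule contours by a second
#' reader: multiplicative log-normal jitter on volume (diameters scale with
#' its cube root), jitter on the diameter ratio and on the logit of the
#' consolidation ratio, and additive Gaussian jitter on the histogram bin
#' locations followed by re-binning (voxels are relocated, never deleted).
#' Zero noise returns an identical cohort.
#'
#' @param cohort an `ssn_cohort`
#' @param reader_noise noise magnitudes (see [generator_config()]); defaults
#'   to the cohort config's `reader_noise`
#' @param seed integer seed for the perturbation stream
#' @return a perturbed `ssn_cohort` with the same ids and class labels
#' @export
perturb_reader <- function(cohort, reader_noise = NULL, seed = NULL) {
  config <- attr(cohort, "config")
  if (is.null(reader_noise)) reader_noise <- config$reader_noise
  if (any(unlist(reader_noise) < 0)) stop("reader noise must be >= 0")
  if (is.null(seed)) seed <- derive_seed(config$seed, "reader")
  withr::with_seed(seed, {
    out <- lapply(cohort, function(rec) {
      f_vol <- exp(stats::rnorm(1, 0, reader_noise$volume_sdlog))
      g <- f_vol^(1 / 3)
      r <- 1 + (rec$max_diameter_mm / rec$min_diameter_mm - 1) *
        exp(stats::rnorm(1, 0, reader_noise$ratio_sdlog))
      m <- rec$mean_diameter_mm * g
      min_d <- 2 * m / (1 + r)
      max_d <- r * min_d
      c_old <- rec$max_consolidation_mm / rec$max_diameter_mm
      c_new <- if (c_old <= 0) 0 else
        stats::plogis(stats::qlogis(clamp(c_old, 1e-6, 1 - 1e-6)) +
                        stats::rnorm(1, 0, reader_noise$consol_sd))
      hist <- rec$histogram
      if (reader_noise$hu_sd > 0) {
        shift <- stats::rnorm(length(hist$bin_centers), 0, reader_noise$hu_sd)
        hcfg <- config$hist
        centers <- hist$bin_centers
        idx <- clamp(round((centers + shift - hcfg$hu_min) / hcfg$bin_width) + 1,
                     1L, length(centers))
        counts <- numeric(length(centers))
        for (j in seq_along(idx)) counts[idx[j]] <- counts[idx[j]] + hist$counts[j]
        hist <- new_histogram(centers, counts)
      }
      rec$volume_mm3 <- rec$volume_mm3 * f_vol
      rec$min_diameter_mm <- min_d
      rec$max_diameter_mm <- max_d
      rec$mean_diameter_mm <- m
      rec$max_consolidation_mm <- c_new * max_d
      rec$histogram <- hist
      rec
    })
    structure(out, class = "ssn_cohort", config = config)
  })
}

#' Write a cohort to plain-text files
#'
#' Writes `cohort.csv` (one row per nodule, histogram excluded), one
#' `<id>_hist.csv` per nodule (columns `hu_bin_center,count`) and the
#' generator config as `config.json`. The round trip through
#' [read_cohort()] is lossless for integers and exact to 1e-9 for reals.
#'
#' @param cohort an `ssn_cohort`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(cohort, function(r)
    data.frame(nodule_id = r$nodule_id, class_label = r$class_label,
               pathology_subtype = r$pathology_subtype,
               volume_mm3 = r$volume_mm3,
               min_diameter_mm = r$min_diameter_mm,
               max_diameter_mm = r$max_diameter_mm,
               mean_diameter_mm = r$mean_diameter_mm,
               max_consolidation_mm = r$max_consolidation_mm)))
  write_csv_full(tab, file.path(dir, "cohort.csv"))
  for (r in cohort) {
    write_csv_full(
      data.frame(hu_bin_center = r$histogram$bin_centers,
                 count = r$histogram$counts),
      file.path(dir, paste0(r$nodule_id, "_hist.csv")))
  }
  cfg <- attr(cohort, "config")
  if (!is.null(cfg))
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `cohort.csv` and the per-nodule histograms
#' @return an `ssn_cohort` (without the generator config attribute unless
#'   `config.json` is present)
#' @export
read_cohort <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(tab)), function(i) {
    h <- utils::read.csv(file.path(dir, paste0(tab$nodule_id[i], "_hist.csv")))
    structure(list(
      nodule_id = tab$nodule_id[i], class_label = tab$class_label[i],
      pathology_subtype = tab$pathology_subtype[i],
      volume_mm3 = tab$volume_mm3[i],
      min_diameter_mm = tab$min_diameter_mm[i],
      max_diameter_mm = tab$max_diameter_mm[i],
      mean_diameter_mm = tab$mean_diameter_mm[i],
      max_consolidation_mm = tab$max_consolidation_mm[i],
      histogram = new_histogram(h$hu_bin_center, h$count)
    ), class = "ssn_nodule")
  })
  cfg_path <- file.path(dir, "config.json")
  cfg <- NULL
  if (file.exists(cfg_path)) {
    cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    cfg$copula <- as.matrix(cfg$copula)
    dimnames(cfg$copula) <- list(latent_names, latent_names)
    class(cfg) <- "ssn_generator_config"
  }
  structure(records, class = "ssn_cohort", config = cfg)
}

# CSV writer at full double precision (17 significant digits round-trips
# IEEE doubles exactly through read.csv).
write_csv_full <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}
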