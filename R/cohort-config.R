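# Per-class calibration constants: published per-class medians (IQRs) of the
# two pathology groups. T1 = pre-invasive / minimally invasive (AAH, AIS,
# MIA); T2 = invasive pulmonary adenocarcinoma (IPA).
class_calibration_targets <- function() {
  list(
    T1 = list(
      volume_mm3      = c(median = 1129, iqr = 2218),
      min_diameter_mm  = c(median = 12,   iqr = 5),
      max_diameter_mm  = c(median = 16,   iqr = 7),
      mean_diameter_mm = c(median = 14,   iqr = 6),
      diameter_ratio   = c(median = 1.37, iqr = 0.40),
      consolidation_ratio = c(median = 0.29, iqr = 0.47),
      mean_hu = c(median = -639, iqr = 169),
      sd_hu   = c(median = 168,  iqr = 70)
    ),
    T2 = list(
      volume_mm3      = c(median = 3459, iqr = 5754),
      min_diameter_mm  = c(median = 15,   iqr = 10),
      max_diameter_mm  = c(median = 25,   iqr = 14.25),
      mean_diameter_mm = c(median = 20,   iqr = 14),
      diameter_ratio   = c(median = 1.67, iqr = 0.57),
      consolidation_ratio = c(median = 0.76, iqr = 0.43),
      mean_hu = c(median = -442, iqr = 225.5),
      sd_hu   = c(median = 250,  iqr = 58)
    )
  )
}

# Marginal sampling parameters for one class, derived in closed form (or by
# 1-D root finding for the logit-normal) from the (median, IQR) targets.
class_marginals <- function(targets) {
  list(
    volume     = lognormal_from_median_iqr(targets$volume_mm3["median"],
                                           targets$volume_mm3["iqr"]),
    mean_diam  = lognormal_from_median_iqr(targets$mean_diameter_mm["median"],
                                           targets$mean_diameter_mm["iqr"]),
    # diameter ratio >= 1: (ratio - 1) is log-normal
    diam_ratio = lognormal_from_median_iqr(targets$diameter_ratio["median"] - 1,
                                           targets$diameter_ratio["iqr"]),
    consol     = logitnormal_from_median_iqr(targets$consolidation_ratio["median"],
                                             targets$consolidation_ratio["iqr"]),
    mean_hu    = list(mean = unname(targets$mean_hu["median"]),
                      sd   = unname(targets$mean_hu["iqr"]) /
                        (2 * stats::qnorm(0.75))),
    sd_hu      = lognormal_from_median_iqr(targets$sd_hu["median"],
                                           targets$sd_hu["iqr"])
  )
}

# Latent base-feature order used by the Gaussian copula.
latent_names <- c("volume", "mean_diam", "diam_ratio", "consol",
                  "mean_hu", "sd_hu")

# Qualitative rank-correlation structure among base features: strong
# volume/diameter coupling, moderate coupling of attenuation summaries with
# each other and with the solid component (consolidation).
default_copula_matrix <- function() {
  R <- matrix(c(
    1.00, 0.85, 0.30, 0.35, 0.35, 0.30,
    0.85, 1.00, 0.30, 0.30, 0.30, 0.25,
    0.30, 0.30, 1.00, 0.20, 0.15, 0.15,
    0.35, 0.30, 0.20, 1.00, 0.55, 0.45,
    0.35, 0.30, 0.15, 0.55, 1.00, 0.55,
    0.30, 0.25, 0.15, 0.45, 0.55, 1.00
  ), 6, 6, dimnames = list(latent_names, latent_names))
  R
}

#' Configuration for the synthetic subsolid-nodule cohort generator
#'
#' Builds the full parameter set for [generate_cohort()]: cohort sizes,
#' per-class marginal distributions calibrated (by closed form on the stated
#' transform scale) to the published per-class medians and IQRs, the
#' attenuation-histogram mixture model, the Gaussian-copula correlation among
#' base features, and the two-reader perturbation magnitudes.
#'
#' @param n_T1,n_T2 nodules per pathology group (defaults 56 and 53)
#' @param seed integer seed; the generator is bit-reproducible given the seed
#' @param bin_width histogram bin width in HU (default 10)
#' @param hu_min,hu_max attenuation support in HU (default -1000 to 500)
#' @param voxel_volume_mm3 voxel volume used to convert nodule volume into a
#'   voxel count (default 0.7 x 0.7 x 2.5 mm reconstruction)
#' @param copula 6x6 positive semi-definite correlation matrix over the base
#'   features (volume, mean diameter, diameter ratio, consolidation ratio,
#'   mean HU, SD HU)
#' @param reader_noise list of perturbation magnitudes for [perturb_reader()]:
#'   `volume_sdlog` (multiplicative log-normal jitter on volume, diameters
#'   scale with its cube root), `ratio_sdlog` (on diameter ratio - 1),
#'   `consol_sd` (additive on the logit of the consolidation ratio) and
#'   `hu_sd` (additive HU jitter on histogram bin locations before
#'   re-binning)
#' @param solid_w0,solid_w1 the solid mixture-component weight for a nodule
#'   with consolidation ratio c is `clamp(solid_w0 + solid_w1 * c, 0.03, 0.45)`
#' @param sgg_frac,ss_frac within-component SDs of the ground-glass and solid
#'   components as fractions of the nodule's target histogram SD
#' @return an object of class `ssn_generator_config`
#' @export
generator_config <- function(n_T1 = 56L, n_T2 = 53L, seed = 1L,
                             bin_width = 10, hu_min = -1000, hu_max = 500,
                             voxel_volume_mm3 = 0.7 * 0.7 * 2.5,
                             copula = default_copula_matrix(),
                             reader_noise = default_reader_noise(),
                             solid_w0 = 0.08, solid_w1 = 0.25,
                             sgg_frac = 0.72, ss_frac = 0.55) {
  targets <- class_calibration_targets()
  cfg <- list(
    n_T1 = as.integer(n_T1), n_T2 = as.integer(n_T2), seed = as.integer(seed),
    targets = targets,
    marginals = list(T1 = class_marginals(targets$T1),
                     T2 = class_marginals(targets$T2)),
    copula = copula,
    hist = list(bin_width = bin_width, hu_min = hu_min, hu_max = hu_max,
                voxel_volume_mm3 = voxel_volume_mm3,
                solid_w0 = solid_w0, solid_w1 = solid_w1,
                sgg_frac = sgg_frac, ss_frac = ss_frac),
    reader_noise = reader_noise,
    # AAH : AIS : MIA subtype mix within T1 (cosmetic, from the published
    # pathology counts)
    t1_subtype_ratio = c(AAH = 3, AIS = 24, MIA = 29)
  )
  class(cfg) <- "ssn_generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Default reader-perturbation magnitudes
#'
#' Calibrated once so that the downstream predicted-class agreement between
#' the two reader variants under the quantile-feature logistic model sits at
#' the published kappa of about 0.95.
#' @return named list of noise magnitudes
#' @export
default_reader_noise <- function() {
  list(volume_sdlog = 0.13, ratio_sdlog = 0.13, consol_sd = 0.20, hu_sd = 15)
}

#' Validate a generator configuration
#' @param cfg an `ssn_generator_config`
#' @return the config, invisibly; errors if invalid
#' @export
validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "ssn_generator_config"))
  if (cfg$n_T1 < 2L || cfg$n_T2 < 2L)
    stop("each class needs at least 2 nodules (CV/ROC undefined below that)")
  R <- cfg$copula
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12))
    stop("copula matrix must be symmetric with unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("copula matrix is not positive semi-definite")
  rn <- cfg$reader_noise
  if (any(unlist(rn) < 0)) stop("reader noise magnitudes must be >= 0")
  with(cfg$hist, {
    stopifnot(bin_width > 0, hu_max > hu_min, voxel_volume_mm3 > 0)
  })
  invisible(cfg)
}
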