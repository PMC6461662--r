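# Replicate-cohort summaries: the emulation-based checks of the generator
# against the published cohort statistics are averages of per-cohort
# statistics over many independently seeded synthetic cohorts.

#' Per-class calibration summary over replicate cohorts
#'
#' Generates `n_cohorts` default cohorts (seeds `base_seed + 1 ... + n`),
#' computes for each the per-class medians of volume, mean HU, IQR HU,
#' consolidation ratio and diameter ratio plus the univariate AUCs of
#' mean HU, log10 volume and diameter ratio, and averages across cohorts.
#'
#' @param n_cohorts number of replicate cohorts (default 200)
#' @param base_seed integer; cohort i uses seed `base_seed + i`
#' @param config_fn function(seed) returning a generator config (defaults to
#'   [generator_config()] with that seed)
#' @return list: `summary` (named means over cohorts), `per_cohort`
#'   (data.frame of the per-cohort statistics)
#' @export
replicate_cohort_summary <- function(n_cohorts = 200L, base_seed = 0L,
                                     config_fn = function(s) generator_config(seed = s)) {
  per <- t(vapply(seq_len(n_cohorts), function(i) {
    ft <- assemble_feature_table(generate_cohort(config_fn(base_seed + i)))
    t1 <- ft$class_label == "T1"
    c(volume_t1 = stats::median(10^ft$log10_volume[t1]),
      volume_t2 = stats::median(10^ft$log10_volume[!t1]),
      mean_hu_t1 = stats::median(ft$mean_hu[t1]),
      mean_hu_t2 = stats::median(ft$mean_hu[!t1]),
      iqr_hu_t1 = stats::median(ft$iqr_hu[t1]),
      iqr_hu_t2 = stats::median(ft$iqr_hu[!t1]),
      consolidation_t1 = stats::median(ft$consolidation_ratio[t1]),
      consolidation_t2 = stats::median(ft$consolidation_ratio[!t1]),
      diameter_ratio_t1 = stats::median(ft$diameter_ratio[t1]),
      diameter_ratio_t2 = stats::median(ft$diameter_ratio[!t1]),
      auc_mean_hu = auc_mann_whitney(ft$mean_hu, ft$class_label),
      auc_log10_volume = auc_mann_whitney(ft$log10_volume, ft$class_label),
      auc_diameter_ratio = auc_mann_whitney(ft$diameter_ratio, ft$class_label))
  }, numeric(13)))
  list(summary = colMeans(per), per_cohort = as.data.frame(per),
       n_cohorts = n_cohorts)
}

#' Mean inter-reader kappa over replicate pipeline runs
#'
#' For each replicate: generate a default cohort, derive its second-reader
#' variant with the default noise, fit the quantile-feature logistic model
#' (model 1) independently on both, and compute Cohen's kappa between the
#' predicted classes at probability 0.5.
#'
#' @inheritParams replicate_cohort_summary
#' @param n_replicates number of replicate runs (default 200)
#' @return list: `mean_kappa`, `kappas` (per replicate)
#' @export
replicate_reader_kappa <- function(n_replicates = 200L, base_seed = 0L,
                                   config_fn = function(s) generator_config(seed = s)) {
  kappas <- vapply(seq_len(n_replicates), function(i) {
    cohort <- generate_cohort(config_fn(base_seed + i))
    cohort_b <- perturb_reader(cohort)
    reader_agreement(assemble_feature_table(cohort),
                     assemble_feature_table(cohort_b),
                     n_bootstrap = 0)$kappa$kappa
  }, numeric(1))
  list(mean_kappa = mean(kappas), kappas = kappas, n_replicates = n_replicates)
}
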