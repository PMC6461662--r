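#!/usr/bin/env Rscript
# Stage 3: functional PCA of the attenuation densities.
#
# Smooths each histogram into a density on [-1000, 500] HU, maps it through
# the log-quantile-density transform, fits FPCA under the trapezoidal inner
# product, joins the FPC scores onto the feature tables, and exports the
# modes-of-variation curves and the FPC1/FPC2 score scatter.

suppressMessages(library(ssnradiomics))

for (reader in c("reader1", "reader2")) {
  cohort <- read_cohort(file.path("results", paste0("cohort_", reader)))
  X <- cohort_lqd(cohort)
  fpca <- fit_fpca(X)
  ft <- read_feature_table(file.path("results",
                                     paste0("features_", reader, ".csv")))
  ft <- add_fpc_scores(ft, fpca)
  write_feature_table(ft, file.path("results",
                                    paste0("features_", reader, ".csv")))
  if (reader == "reader1") {
    write_fpca_json(fpca, "results/fpca_model.json")
    ve <- cumsum(fpca$eigenvalues) / sum(fpca$eigenvalues)
    cat(sprintf("FPCA: K = %d components explain %.1f%% of the variation\n",
                fpca$K, 100 * ve[fpca$K]))
    modes <- do.call(rbind, lapply(1:2, function(k) {
      mv <- mode_of_variation(fpca, k)
      do.call(rbind, lapply(names(mv), function(lv)
        data.frame(component = k, level = lv, hu = mv[[lv]]$grid,
                   density = mv[[lv]]$values)))
    }))
    write.csv(modes, "results/mode_of_variation.csv", row.names = FALSE)
    write.csv(data.frame(nodule_id = ft$nodule_id,
                         class_label = ft$class_label,
                         fpc1 = ft$fpc1, fpc2 = ft$fpc2),
              "results/fpc_scores.csv", row.names = FALSE)
    y <- as.integer(ft$class_label == "T2")
    cat(sprintf("FPC1 point-biserial r with invasiveness: %.2f (FPC2: %.2f)\n",
                cor(ft$fpc1, y), cor(ft$fpc2, y)))
  }
}
cat("wrote results/fpca_model.json, mode_of_variation.csv, fpc_scores.csv\n")
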