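#!/usr/bin/env Rscript
# Stage 2: a-priori imaging features.
#
# Computes, for every nodule of both reader variants, the histogram moments
# (mean, SD, skewness, Pearson kurtosis), the upper attenuation quantiles
# (Q.50, Q.75, Q.875) and IQR, the consolidation ratio, log10 volume,
# diameters and the max/min diameter ratio, and prints the per-class median
# (IQR) summary of the first reader's table.

suppressMessages(library(ssnradiomics))

for (reader in c("reader1", "reader2")) {
  cohort <- read_cohort(file.path("results", paste0("cohort_", reader)))
  ft <- assemble_feature_table(cohort)
  write_feature_table(ft, file.path("results", paste0("features_", reader, ".csv")))
}

ft <- read_feature_table("results/features_reader1.csv")
t1 <- ft$class_label == "T1"
summarize <- function(x) sprintf("%.2f (%.2f)", median(x), IQR(x))
cat("per-class median (IQR), reader 1:\n")
for (f in c("mean_hu", "sd_hu", "iqr_hu", "q875_hu", "consolidation_ratio",
            "log10_volume", "diameter_ratio")) {
  cat(sprintf("  %-20s T1 %s | T2 %s\n", f,
              summarize(ft[[f]][t1]), summarize(ft[[f]][!t1])))
}
cat("wrote results/features_reader1.csv and results/features_reader2.csv\n")
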