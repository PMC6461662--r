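#!/usr/bin/env Rscript
# Stage 5: inter-reader reproducibility.
#
# Fits the quantile-feature logistic model (model 1) independently on the
# two reader variants and quantifies agreement of the predicted classes
# (Cohen's kappa, threshold 0.5) and predicted probabilities (ICC(2,1),
# absolute agreement), both with percentile bootstrap CIs over subjects.

suppressMessages(library(ssnradiomics))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2] else 42)

ft_a <- read_feature_table("results/features_reader1.csv")
ft_b <- read_feature_table("results/features_reader2.csv")
ag <- reader_agreement(ft_a, ft_b, n_bootstrap = 2000L, seed = seed)
write_agreement_json(ag, "results/agreement.json")

cat(sprintf("predicted-class kappa: %.3f [%.3f %.3f]\n",
            ag$kappa$kappa, ag$kappa$ci_low, ag$kappa$ci_high))
cat(sprintf("predicted-probability ICC(2,1): %.3f [%.3f %.3f]\n",
            ag$icc$icc, ag$icc$ci_low, ag$icc$ci_high))
cat("discordant nodules:",
    if (length(ag$discordant)) paste(ag$discordant, collapse = ", ")
    else "none", "\n")
cat("wrote results/agreement.json\n")
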