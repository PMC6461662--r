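#!/usr/bin/env Rscript
# Stage 1: draw the synthetic two-reader cohort.
#
# Generates the default 109-nodule cohort (56 pre-invasive/minimally
# invasive T1, 53 invasive T2) whose per-class feature distributions are
# calibrated to the published cohort statistics, plus its second-reader
# variant under the default contour-correction noise, and writes both as
# per-nodule histogram CSVs + cohort tables under results/.

suppressMessages(library(ssnradiomics))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2] else 42)

cfg <- generator_config(seed = seed)
cohort <- generate_cohort(cfg)
cohort_b <- perturb_reader(cohort)

write_cohort(cohort, "results/cohort_reader1")
write_cohort(cohort_b, "results/cohort_reader2")

labels <- vapply(cohort, function(r) r$class_label, character(1))
vol <- vapply(cohort, function(r) r$volume_mm3, numeric(1))
cat(sprintf("cohort: %d nodules (%d T1, %d T2), seed %d\n",
            length(cohort), sum(labels == "T1"), sum(labels == "T2"), seed))
cat(sprintf("median volume: T1 %.0f mm^3, T2 %.0f mm^3\n",
            median(vol[labels == "T1"]), median(vol[labels == "T2"])))
cat("wrote results/cohort_reader1 and results/cohort_reader2\n")
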