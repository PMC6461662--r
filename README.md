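# ssnradiomics

Classification of subsolid lung nodules (SSN) as invasive versus
pre-invasive/minimally-invasive adenocarcinoma from CT attenuation
histograms and geometric measurements — an analysis pipeline for
radiologists and imaging scientists working with histogram exports from
clinical nodule-analysis software.

A subsolid nodule's attenuation histogram (voxel counts over Hounsfield-unit
bins on [−1000, 500] HU) carries the signature of invasiveness: invasive
lesions (IPA, class T2) are larger, more heterogeneous, and shifted toward
higher attenuation than pre-invasive or minimally invasive lesions
(AAH/AIS/MIA, class T1). The pipeline quantifies this two ways:

* **A-priori features**: count-weighted histogram moments (mean, SD,
  skewness, Pearson kurtosis), upper quantiles Q.50 / Q.75 / Q.875 and IQR
  by uniform-within-bin interpolation, the consolidation ratio (max solid
  diameter / max tumor diameter), log₁₀ volume, and the max/min diameter
  ratio.
* **Data-driven features**: functional principal component scores (FPC1,
  FPC2) of the smoothed attenuation density. Each histogram is smoothed to
  a density f on [−1000, 500] HU, mapped through the log-quantile-density
  transform lqd(p) = −log f(Q(p)) = log dQ/dp into an unconstrained
  function space, and FPCA is performed there under the trapezoidal inner
  product, so every mode of variation maps back to a valid density.

Screening uses Mann–Whitney ROC-AUC (exactly equal to pairwise counting
with ties ½) with Youden-index operating thresholds and a Pearson/Fisher-Z
correlation screen. Three fixed logistic models (1: Q.875 + IQR + volume +
diameter ratio; 2: FPC1 + volume + diameter ratio; 3: FPC1 + FPC2 +
volume) are evaluated by repeated stratified 10-fold cross-validation (100
repeats) with bootstrap optimism-corrected calibration curves.
Inter-reader reproducibility is quantified by Cohen's kappa on predicted
classes and ICC(2,1) on predicted probabilities between two reader-variant
cohorts.

Because the underlying patient data are not public, the package includes a
seeded synthetic cohort generator (56 T1 + 53 T2 nodules by default) whose
per-class marginals — volume, diameters, diameter ratio, consolidation
ratio, histogram mean/SD — are calibrated in closed form to the published
per-class medians and IQRs, coupled through a Gaussian copula, with
histograms drawn from per-nodule truncated two-component Gaussian mixtures.
See the vignette (`vignettes/subsolid-nodule-classification.Rmd`) for the
model, its assumptions, and what the synthetic cohort does and does not
emulate.

## Worked example

The analysis is organised as numbered stage scripts over the package
functions; each stage writes plain-text tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 42   # cohort + second-reader variant
Rscript analysis/02_features.R             # a-priori feature tables
Rscript analysis/03_fpca.R                 # density FPCA, scores, modes
Rscript analysis/04_models.R --seed 42     # screening + CV models
Rscript analysis/05_agreement.R --seed 42  # inter-reader agreement
```

Output of the stages (seed 42):

```
cohort: 109 nodules (56 T1, 53 T2), seed 42
median volume: T1 1302 mm^3, T2 2967 mm^3

FPCA: K = 2 components explain 88.1% of the variation
FPC1 point-biserial r with invasiveness: 0.52 (FPC2: 0.15)

univariate screening (top 6 of 16 predictors):
  parameter   auc ci_low ci_high best_threshold
1    iqr_hu 0.829  0.747   0.905       273.7718
2     sd_hu 0.820  0.737   0.897       214.7507
3      fpc1 0.815  0.730   0.893         0.0822
4   q875_hu 0.805  0.713   0.885      -252.9587
5    q75_hu 0.794  0.699   0.880      -405.0742
6   mean_hu 0.768  0.671   0.859      -472.0168

repeated 10-fold CV (100 repeats):
   model   auc auc_lo auc_hi accuracy calibration_error
1 model1 0.799  0.784  0.809    0.733            0.0147
2 model2 0.795  0.782  0.806    0.768            0.0485
3 model3 0.802  0.790  0.813    0.729            0.0250

predicted-class kappa: 0.908 [0.816 0.982]
predicted-probability ICC(2,1): 0.994 [0.990 0.996]
```

Reading this: two functional components capture ~88% of the variation
among attenuation curves; attenuation heterogeneity features (IQR, SD,
FPC1) dominate the univariate ranking while geometric features rank lower;
the three parsimonious logistic models perform similarly (CV AUC ≈ 0.80 on
this single synthetic cohort); and the pipeline's predicted classes are
highly reproducible between the two simulated readers. On a single
109-nodule draw these numbers move a few points from seed to seed — the
calibrated quantities are the replicate-cohort averages below.

The same functions run on one in-memory cohort:

```r
library(ssnradiomics)
cohort <- generate_cohort(generator_config(seed = 42))
ft  <- assemble_feature_table(cohort)
fp  <- fit_fpca(cohort_lqd(cohort))
ft  <- add_fpc_scores(ft, fp)
univariate_auc(ft$fpc1, ft$class_label)
evaluate_models(ft, seed = 42)
```

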