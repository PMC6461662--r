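---
title: "Classifying subsolid lung nodules from CT attenuation histograms"
author: "ssnradiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying subsolid lung nodules from CT attenuation histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Subsolid lung nodules (SSN) — ground-glass nodules with or without a solid
component — span the adenocarcinoma invasiveness spectrum, from atypical
adenomatous hyperplasia (AAH) and adenocarcinoma in situ (AIS) through
minimally invasive (MIA) to frankly invasive pulmonary adenocarcinoma
(IPA). Distinguishing invasive (T2 = IPA) from pre-invasive or minimally
invasive (T1 = AAH/AIS/MIA) lesions on CT matters clinically: invasive
lesions warrant resection, the rest can often be surveilled.

This package implements, as a tested and reusable pipeline, an analysis that
makes that call from two cheap inputs a clinical workstation already
produces: the nodule's CT attenuation histogram (voxel counts over
Hounsfield-unit bins) and a handful of geometric measurements (volume,
diameters, maximum solid-component size). No patient data ship with the
package; a calibrated synthetic cohort generator stands in for the study
population, and everything downstream operates identically on real exported
histograms.

## The synthetic cohort generator

The generator draws two classes of nodules (56 T1, 53 T2 by default) whose
per-class distributions are calibrated, in closed form on a stated transform
scale, to published per-class medians and inter-quartile ranges:

* **Volume** is log-normal per class (medians 1129 / 3459 mm³). A positive,
  right-skewed quantity with closed-form calibration from (median, IQR);
  this choice also makes the log₁₀-volume operating threshold of ~3.11
  (≈1290 mm³) fall between the class medians, as it should.
* **Mean diameter** is log-normal (14 / 20 mm); the max/min **diameter
  ratio** minus one is log-normal (ratios 1.37 / 1.67). Minimum and maximum
  diameters are then derived as `min = 2·mean/(1+r)`, `max = r·min`, which
  reproduces the published per-class minimum (12 / 15 mm) and maximum
  (16 / 25 mm) diameter medians — the published geometry is internally
  consistent with this construction.
* **Consolidation ratio** (max solid diameter / max tumor diameter) is
  logit-normal (medians 0.29 / 0.76), the natural two-parameter family on
  [0, 1]; its scale is solved by monotone root finding.
* **Histogram shape**: each nodule's attenuation histogram is drawn from a
  two-component Gaussian mixture truncated to [−1000, 500] HU — a dominant
  ground-glass component plus a higher-attenuation solid component whose
  weight grows with the consolidation ratio (w = 0.08 + 0.25·c, clamped to
  [0.03, 0.45]). Given a nodule's target histogram mean (normal per class:
  −639 / −442 HU) and SD (log-normal: 168 / 250 HU), the component
  locations are solved so the untruncated mixture matches both exactly; the
  within-component SD fractions (0.72 and 0.55 of the target SD) were fixed
  once so that the emergent attenuation IQR and skewness/kurtosis medians
  sit near their published values. This makes T1 histograms low-attenuation
  and right-skewed and T2 histograms heterogeneous and closer to bimodal,
  which is exactly the contrast the downstream features exploit.
* **Correlation** among the six base features is induced by a Gaussian
  copula, which preserves the calibrated marginals exactly. The correlation
  matrix encodes the qualitative structure of the published correlogram:
  strong volume–diameter coupling, moderate coupling among attenuation
  summaries and consolidation, weak elsewhere.
* **Voxel counts**: total voxels = volume / voxel volume with a default
  0.7 × 0.7 × 2.5 mm voxel, giving a realistic count scale (and hence a
  realistic sampling-noise scale) for the histograms. The default bin width
  is 10 HU over [−1000, 500] (151 bins); the true export bin width of the
  workstation is unknown, so it is configuration-exposed.
* **Second reader**: manual contour correction by an independent reader is
  emulated by multiplicative log-normal jitter on volume (diameters scale
  with its cube root), jitter on the diameter ratio and the logit of the
  consolidation ratio, and additive Gaussian jitter on histogram bin
  locations followed by re-binning, which relocates voxels but never
  deletes them. The default magnitudes (volume sdlog 0.13, ratio sdlog
  0.13, consolidation logit sd 0.20, 15 HU) were tuned once so that the
  downstream predicted-class agreement under model 1 sits at kappa ≈ 0.95,
  which is the only agreement level the source analysis reports.

What the generator deliberately does **not** emulate: spatial structure
(there is no voxel phantom and no segmentation), scanner and reconstruction
effects, vessels or cavitation inside the ROI, and any within-class
pathology substructure (the AAH/AIS/MIA subtype labels are cosmetic, drawn
3:24:29). Passing tests therefore show that the analysis chain is correct
and that the published per-class summary statistics imply the published
univariate discriminations — not that the pipeline performs at any stated
level on real patients.

## A-priori histogram features

Features are computed directly from the binned histogram: count-weighted
**population** moments over bin centers (the convention must be fixed for
exact oracles, and voxel counts are large enough that the n−1 correction is
immaterial), with **Pearson kurtosis** (Gaussian = 3, consistent with
published per-class kurtosis medians of ~2.5–3.2); and weighted quantiles
(Q.50, Q.75, Q.875, IQR) under **uniform-within-bin interpolation** —
i.e. linear inversion of the piecewise-linear CDF — because the input is a
histogram, not a raw sample. Zero-spread histograms are an error when
standardized moments are requested, not a silent NaN.

## Density FPCA in the log-quantile-density domain

The data-driven features are functional principal component scores of the
attenuation distribution. Densities live on a constrained manifold
(non-negative, unit mass), so the pipeline performs FPCA after the
log-quantile-density (LQD) transform, which maps a density *f* with
quantile function *Q* to the unconstrained curve

> lqd(p) = −log f(Q(p)) = log q(p),  q = dQ/dp,

on the probability grid. Linear operations in this domain map back to valid
densities, so modes of variation are always legitimate attenuation
distributions.

Numerical choices, all deterministic:

* **Smoothing**: Gaussian kernel on the count-weighted bin centers with
  boundary reflection at −1000 and 500 HU (no mass leaks off the support);
  bandwidth defaults to Silverman's rule on the weighted sample. Any
  smooth, mass-preserving estimator satisfies the downstream contracts, so
  the smoother and bandwidth are configuration-exposed.
* **Floor**: densities are floored at δ = 1e−5 per HU and renormalized, so
  the LQD is finite on the whole support.
* **Grids**: 151 HU points, 101 probability points by default.
* **Inverse transform**: q(p) spans several orders of magnitude near the
  support boundary, so the inverse integrates exp(lqd) with spline
  refinement in the (smooth) LQD domain followed by log-linear
  exponential-fit quadrature, then rescales the quantile range to the full
  1500 HU support. For densities bounded away from the floor the round
  trip is accurate to L1 ≈ 1e−4; where a density rides the floor over a
  long HU stretch the boundary spike of q(p) is not resolvable from 101
  samples and reconstruction is only approximate there. This limitation is
  intrinsic to the discretized transform, affects only density-space
  reconstructions (modes of variation), and does not touch the FPC scores,
  which are computed entirely in the LQD domain.
* **FPCA**: eigendecomposition of the sample covariance operator under the
  trapezoidal inner product, covariance normalized by n−1. The number of
  components is the smallest K with cumulative variance explained ≥ 0.85
  (minimum 2); on default synthetic cohorts two components explain ~87–88%
  of the variation. Eigenfunction signs are inherently arbitrary, and the
  source analysis is itself internally inconsistent about the orientation
  of its first component, so this package fixes its own convention rather
  than forcing a match: each eigenfunction has positive integral (positive
  inner product with the constant upward-shift direction, which for FPC1
  means higher scores ↔ wider, more heterogeneous, higher-attenuation
  distributions), with ties broken by a positive value at p = 0.5.
* **Modes of variation** walk the LQD space from the mean along one
  eigenfunction by the empirical score quantiles {0.1, 0.25, 0.5, 0.75,
  0.9} and map back to densities.

## Modeling

* **Univariate screening**: Mann–Whitney rank AUC (ties ½, exactly equal to
  exhaustive pairwise counting), direction chosen so AUC ≥ 0.5, stratified
  percentile bootstrap CI (2000 resamples; the source's CI method is
  unstated, so the bootstrap is the package's documented choice), and
  Youden-optimal thresholds over midpoints between adjacent distinct
  values, smallest threshold on ties.
* **Correlation screen**: Pearson r with two-sided Fisher-Z p-values;
  pairs with |r| ≥ 0.9 are flagged together with the lower-AUC member as
  the discard candidate. Zero-variance columns are excluded, not fatal.
* **Logistic models**: three fixed predictor sets — Q.875 + IQR + volume +
  diameter ratio; FPC1 + volume + diameter ratio; FPC1 + FPC2 + volume —
  fitted by maximum likelihood on internally standardized predictors
  (training-fold statistics only inside CV; standardization is immaterial
  to AUC but material to convergence). Perfect separation is surfaced as a
  warning with a finite iteration cap.
* **Evaluation**: repeated stratified 10-fold cross-validation (100
  repeats), folds redrawn each repeat from a per-repeat stream derived
  from the master seed. AUC is computed on the pooled out-of-fold
  probabilities of each repeat; accuracy/sensitivity/specificity use a
  fixed 0.5 threshold (unstated in the source; documented here). Point
  estimates are means over repeats and intervals are the 2.5/97.5
  percentiles of the repeat-level metrics — the source's interval method
  for its CV table is unstated, and its exact evaluation split is
  ambiguous (its accuracy CI suggests a small hold-out that is never
  described), so this package reports repeated-CV metrics only.
* **FPC scores** are computed once on the full cohort before CV, mirroring
  the source analysis; this is a mild information leak, and the leakage-free
  per-fold alternative is possible with the exposed building blocks, but
  the default reproduces the source's procedure.
* **Calibration**: bootstrap optimism-corrected lowess calibration curve
  (Harrell-style resampling validation, 200 refits by default, minimum 20);
  the mean absolute calibration error averages |corrected − predicted| over
  the sample.

## Inter-reader agreement

Model 1 is fitted independently on the two reader variants; agreement of
predicted classes uses Cohen's kappa and agreement of predicted
probabilities uses ICC(2,1) — two-way random effects, absolute agreement,
single measure, the stricter standard flavor for probability concordance
(the source states only "ICC"). Both CIs are percentile bootstraps that
resample subjects (pairs), never raters. Agreement is computed on the full
cohort; which "testing dataset" the source used for its own kappa is
unclear, and this choice is documented rather than guessed.

## Problem sizes and determinism

The emulation-based checks average per-cohort statistics over 200
independently seeded replicate cohorts of 109 nodules, the scale at which
per-class medians stabilize well inside the calibration tolerances.
Property checks use small exactly solvable constructions (20 curves × 21
grid points against a brute-force covariance eigendecomposition; n = 500
binormal designs; n = 2000–5000 parameter-recovery fits). Every stochastic
stage consumes a named sub-stream derived from one master seed — cohort
draw, reader perturbation, each CV repeat, each bootstrap — so changing,
say, the bootstrap count cannot perturb the cohort, and identical
seed + configuration reproduces every output byte for byte.

## Known limitations

* The synthetic cohort matches published *marginal* summaries and a
  qualitative correlation structure; joint-distribution features beyond
  that (and therefore multivariable model AUCs) are emergent, not
  calibrated, and land somewhat below the source's reported multivariable
  performance.
* The LQD inverse is approximate for densities that ride the floor (see
  above).
* Histogram bin width and the voxel-count convention of the original
  export are unknown; both are configuration-exposed stand-ins.
* Agreement is modeled at the measurement-perturbation level only; real
  inter-reader variability has spatially structured causes this does not
  represent.
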