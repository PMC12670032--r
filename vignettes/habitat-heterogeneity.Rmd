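---
title: "Habitat-based tumor heterogeneity: models, parameters and design choices"
author: "habheter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat-based tumor heterogeneity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind **habheter**, the
parameters that matter, what the synthetic phantom emulates (and what it
does not), and the numerical and design decisions that were genuinely open.

## The heterogeneity model

The premise is that diffuse, whole-lesion radiomics averages away the
spatial organisation of a tumor and its rim. Instead, each spatial scope —
the tumor and cumulative peritumoral shells at 3, 5 and 7 mm — is decomposed
into $K$ *habitats*: contiguous subregions with coherent multisequence
intensity. For each of the 107 standard radiomic features $i$, computed per
habitat and per sequence, heterogeneity is summarised as the coefficient of
variation across habitats,

$$\mathrm{CV}_i = \frac{\mathrm{SD}_i}{\lvert \overline{x}_i \rvert},$$

so 0 means the feature is identical in every habitat and larger values mean
a more uneven spatial distribution. Stacking 107 features × 4 sequences ×
4 regions gives a 1712-entry case signature. The assumptions are that
(a) the mask delineates the lesion on a common grid for all sequences,
(b) intensities are comparable across cases only after per-sequence
z-scoring, and (c) a fixed habitat count makes CVs comparable across cases
— which is why the encoder *guarantees* exactly
$K_\text{eff} = \min(K, n_\text{voxels})$ habitats rather than accepting
whatever a supervoxel pass returns.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| target spacing | 1 × 1 × 3 | mm | common liver-MRI slice anisotropy; all geometry is computed in physical mm |
| band distances | 3, 5, 7 | mm | cumulative 0–d shells outside the tumor |
| habitat count $K$ | 50 | – | the working habitat resolution; stability is assessed at 30–70 |
| SLIC compactness | 0.1 | – | spatial-vs-intensity weight on z-scored channels; 0.1 keeps habitats contiguous without ignoring intensity |
| discretisation bin width | 0.1 | z-score units | fixed bin width on normalized intensities for all texture classes |
| ICC threshold | 0.800 | – | reproducibility filter across repeated segmentations |
| univariate α | .05 | – | per-feature filter, deliberately uncorrected (a screening step) |
| top-k | 20 | features | tree-importance final cut |
| split ratio | 7:3 | – | stratified, largest-remainder per-class apportionment |
| RMST τ | 36, 60 | months | 3- and 5-year summaries |

## Normalization and discretisation

The normalization scope is the whole resampled volume, per sequence
(z-score). This is sequence-agnostic and robust without organ masks, at the
cost of sensitivity to how much non-liver anatomy the field of view
contains. Texture discretisation uses a fixed bin width of 0.1 on the
z-scored intensities, anchored at the ROI minimum; note that under fixed
bin width the number of grey levels grows with the ROI's intensity range,
so range-linked texture features legitimately track dispersion.

## The habitat encoder

Masked SLIC runs on the four normalized channels with the spatial distance
measured in mm (the 3 mm slice spacing is honoured), seeds placed by
deterministic farthest-point sampling, and ten assignment/update
iterations. Supervoxel passes do not guarantee an exact cluster count, so a
post-pass (i) relabels connected components, (ii) folds the smallest
component into its face-adjacent neighbour with the largest shared boundary
until the count is met, and (iii) if ever short, splits the largest
component by peeling its voxel farthest from the centroid. Ties break
deterministically (more shared faces, then lower id; final ids ordered by
first voxel in array order), so the encoding is reproducible run to run.
"Texture" enters clustering implicitly through SLIC's joint
spatial-intensity geometry; explicit texture maps are not clustering
channels.

## Feature extraction conventions

All 107 features follow the standard reference definitions. Three
conventions deserve note. Texture matrices (GLCM, GLRLM) are accumulated
over the 13 unique 3D directions and features are computed once on the
merged matrix, rather than averaging per-angle features; on the small,
near-isotropic-statistics ROIs involved the two conventions differ
negligibly, and the merged form is cheaper and simpler to test against
brute-force loops. Shape features are computed once per habitat mask
(voxel-based volume, exposed-face surface area, covariance-eigenvalue axis
lengths) and replicated across sequences, honouring the 107 × 4
bookkeeping. ROIs smaller than 3 voxels get `NA` for every texture cell —
never a silent zero — and the CV step excludes missing cells pairwise;
habitats that small cannot support co-occurrence statistics, and imputing
them would fabricate homogeneity or heterogeneity.

Degenerate-value conventions: GLCM Correlation on a single-level ROI is 1
(its flat-field limit); moment ratios (skewness, kurtosis, elongation,
flatness) on constant or single-voxel ROIs are `NA`; the CV returns `NA`
when fewer than two non-missing habitat values remain or when
$\lvert\overline{x}\rvert < 10^{-8}$, deferring cohort-median imputation to
the modeling stage so that selection statistics are computed on train rows
only.

## Selection and modeling

The ICC filter uses ICC(2,1) — two-way random effects, absolute agreement,
single measure — computed from the ANOVA closed form; the same estimator
serves the across-K stability analysis with K settings as raters. The
univariate step tests each feature with a Student *t* test when
Shapiro-Wilk accepts normality in both groups (α = .05, per feature) and a
Mann-Whitney U otherwise. The tree step fits a single Gini decision tree
(no surrogate or competing splits, so importance is pure primary-split
impurity reduction) and takes the top 20, ties broken by name.

The "DNN" is a two-hidden-layer perceptron (64/32, ReLU, dropout 0.2)
trained with Adam (learning rate 1e-2, batch 16, up to 300 epochs) and
early stopping on a 20% train-internal validation split scored by AUC.
Because such small validation sets saturate the AUC quickly, equal-AUC ties
are broken by validation cross-entropy when selecting the best epoch; with
a pure-AUC rule the kept weights are effectively the first epoch that
happens to rank the handful of validation cases correctly, which is close
to the initialisation. All learners share one seed, fixed library defaults
and train-statistics standardisation; there is no tuning loop.

The operating threshold is the Youden-optimal point on the *training* ROC,
frozen for all splits — this is what produces the asymmetric
sensitivity/specificity pairs typical of such pipelines. Calibration error
is the 10-bin equal-width expected calibration error. AUC is the
trapezoidal area over the tie-grouped ROC (cross-checked against an
independent ROC implementation in the tests).

## Survival

Kaplan-Meier, log-rank and Cox (Efron ties) are delegated to the standard
survival machinery; medians use the first time the curve reaches 0.5 with
Brookmeyer-Crowley-style CIs, reported as `NA` while the curve stays above
0.5. RMST is the area under the KM step up to τ with the integrated
Greenwood variance
$\widehat{\mathrm{Var}} = \sum_i A_i^2\, d_i / \{n_i (n_i - d_i)\}$ where
$A_i$ is the remaining area from the $i$-th event time to τ; group
contrasts use a normal approximation on the difference. Reported hazard
ratios are univariable by default.

## What the phantom emulates — and what it does not

A phantom case is an ellipsoidal tumor (semi-axes 8–13 mm) in a
64 × 64 × 24 grid at 1 × 1 × 3 mm. Its four channels are distinct affine
mixes of a shared Gaussian random field (correlation length 4 mm), a
longer-range "subregion" field (10 mm) that creates habitat-like patches, a
smooth background field, a peritumoral enhancement halo (an exponentially
decaying intensity offset, amplitude 1, 10 mm constant), per-sequence tumor
contrast of alternating sign, and right-skewed exponential voxel noise
emulating magnitude-MR statistics. The class effect is deliberately
*peritumorally dominant*: texture variance ratio 1.5 in the tumor versus 6
in the band, and a stronger subregion field (weight 1.0 vs 0.4) in the
high-heterogeneity class — the mechanism the framework is supposed to
detect is spatially structured heterogeneity around the lesion, which a
whole-tumor feature vector cannot see. Two design details exist purely for
statistical sanity of the CV: the halo keeps the across-habitat means of
sign-bearing first-order features (mean, extremes, percentiles) bounded
away from zero, and the skewed noise does the same for skewness; without
them those CVs explode in both classes for denominator reasons unrelated
to heterogeneity. Labels follow a fixed 25% prevalence
(`round(prevalence * n)` positives), observer masks are smooth
signed-distance perturbations (1 mm default), and survival is Weibull
(shape 1.3, scale 60 months) with class hazard ratios 2.79 (overall) and
2.17 (recurrence-free) under uniform 24–84-month administrative censoring.

The phantom does not emulate liver anatomy, vessels, partial-volume or
bias fields, inter-sequence misregistration, or scanner-specific intensity
distributions. Passing tests therefore show that the *pipeline* measures
spatially structured heterogeneity correctly and that its statistics are
calibrated — not that any particular clinical effect size is reproduced.

## Problem sizes used in validation

The validation suite runs a 120-case default-geometry cohort (30
high-heterogeneity cases, matching a 30-per-class comparison), a 30-case
stability analysis across K ∈ {30, 40, 50, 60, 70}, 12 paired
resampling seeds for the TH-versus-Rad comparison, 500 replicates for Cox
coverage at n = 275, and 2000-draw closed-form checks for RMST; the
end-to-end pipeline example uses 20 cases. These sizes were chosen so every
property check retains a comfortable statistical margin while a full run
stays in the minutes range on a single CPU.

## Known limitations

* Bands are cumulative shells and are not clipped to any organ mask;
  near-surface lesions include extrahepatic voxels in their bands (a
  warning is emitted when the tumor touches the image border).
* Exactly-K enforcement can fail only when a region mask is fragmented into
  more than K disconnected islands; this raises an informative error
  rather than silently returning fewer habitats.
* Mesh-based shape quantities are approximated voxel-wise (count × volume;
  exposed-face surface area), which biases sphericity slightly low on
  coarse grids; comparisons across cases on a fixed grid are unaffected.
* The CV is undefined near zero means by construction; the near-zero guard
  reports such cells as missing rather than propagating huge ratios into
  selection.
* With ~30 positives per cohort the DNN remains the highest-variance
  learner in the suite even with early stopping; conclusions in the tests
  are therefore paired and rank-based rather than absolute AUC thresholds.
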