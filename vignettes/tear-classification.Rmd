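---
title: "Quantitative tear classification in shoulder ultrasound: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative tear classification in shoulder ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonotear)
```

## The problem and the model

A torn supraspinatus tendon reads on ultrasound as a focal hypoechoic
defect; non-tear tendinopathy reads as a heterogeneous, relatively
hyperechoic thickening. `sonotear` turns that radiological intuition
into numbers. Each case is an 8-bit grayscale image, a delineated
lesion mask, and a label (`tendinopathy` / `tear`). The pipeline
computes 4 histogram-moment intensity features and 14 co-occurrence
texture features of the masked tissue, screens them univariately, and
classifies with a backward-eliminated logistic regression evaluated by
leave-one-out cross-validation (LOOCV).

The classifier is the logistic tear-probability model

$$P(\mathrm{tear}) = \frac{1}{1 + \exp\left(-\left(\sum_i f_i C_i - \mathrm{constant}\right)\right)},$$

with raw-scale features $f_i$, coefficients $C_i$ and a scalar offset.
Cases with $P \ge 0.5$ are called tears. Performance is summarized by
accuracy, sensitivity, specificity, PPV, NPV (positive class = tear)
and the empirical area under the ROC curve.

## Feature definitions and their conventions

**Moments.** Population (divide-by-$n$) central moments of the masked
gray levels; skewness $m_3/m_2^{3/2}$; kurtosis is the *non-excess*
$m_4/m_2^2$, so a Gaussian lesion scores 3. These conventions are
deliberate: lesion ROIs contain thousands of pixels, so small-sample
bias corrections are immaterial, and the non-excess form is the one
under which a near-Gaussian tendinopathy histogram sits at its
reference value 3. For a constant region, skewness and kurtosis are
undefined and reported as `NA` — never silently zero.

**Quantization.** `level = floor(value * G / 256)` with $G = 8$: equal
32-value bins, monotone, endpoints 0 -> 0 and 255 -> 7. Eight levels
retain the contrast a reader can distinguish while keeping the $8
\times 8$ co-occurrence matrix well populated in small lesions.

**Co-occurrence matrices.** Distance $d = 1$ (fine fibrillar detail;
some lesions are under half a centimeter), directions
$\theta \in \{0^\circ, 45^\circ, 90^\circ, 135^\circ\}$ with offsets
$(0,+d), (-d,+d), (-d,0), (-d,-d)$. Counting is *symmetric* (each pair
increments $(i,j)$ and $(j,i)$), which guarantees well-defined
marginals, and a pair contributes only when **both** pixels are inside
the mask, so background echo never leaks into the lesion statistics.
Each directed matrix is normalized to probabilities first; the 14
statistics are computed per direction and then averaged — features,
not matrices, are averaged.

**The 14 statistics.** Autocorrelation, Contrast, Correlation, Cluster
Prominence, Cluster Shade, Dissimilarity, Energy, Entropy, Homogeneity,
Difference Variance, Difference Entropy, the first Information Measure
of Correlation, Inverse Difference Normalized (IDN) and Inverse
Difference Moment (IDM). Entropies use the natural log by default
(`base` argument; base changes scale, never ranking). The inverse
difference forms are the *normalized* variants dividing $|i-j|$ by $G$
(and $(i-j)^2$ by $G^2$): their values then exceed Homogeneity, which
is the only reading consistent with clinically reported magnitudes
(IDN ~0.999, IDM ~0.9998 versus Homogeneity ~0.997). Correlation and
the information measure are undefined (`NA`) for constant regions.

A structural property worth knowing: when the lesion is homogeneous
enough that level differences $|i-j|$ only take a few values, several
of these statistics (Homogeneity, IDN, IDM, Contrast, Dissimilarity)
become *exact* affine combinations of the same few difference
probabilities. The feature family is then rank-deficient to machine
precision at any sample size. `fit_logistic()` refuses such designs
with an explicit error naming the features; the pipeline stage
`ctc_train_eval()` instead prunes aliased features up front (with a
message naming them) — the same division of labor as a modeling
function erroring on singular designs while the preprocessing layer
removes linear combinations.

## Statistical screening

Each feature's two class samples are tested for normality with a
one-sample Kolmogorov-Smirnov test against a normal law with
sample-estimated mean and SD. Estimating parameters from the same
sample is the Lilliefors situation; the plain test's p-values are then
biased, so a Lilliefors-corrected option (`lilliefors = TRUE`, via
`nortest`) is provided. The t-test (classic pooled-variance Student
form; Welch by flag) is used only when **both** groups pass at 0.05,
otherwise the Mann-Whitney U-test — exact for small tie-free samples,
normal approximation with tie correction otherwise. Significance is
declared at $\alpha = 0.05$ with *no* multiple-testing correction:
the screen is a transparency report, and the classifier's feature
selection does not consume it, so inflating per-family error here
costs nothing downstream.

## Fitting, selection, validation

The logistic model is fitted by Newton-Raphson on the log-likelihood
(convergence: change below $10^{-8}$; at most 100 iterations;
step-halving). Complete separation — common in small, clean datasets —
has no finite optimum; it is detected (non-convergence or near-zero
deviance) and the model is refitted with a tiny ridge penalty
($10^{-6}$) and flagged `separated`. Flat (aliased) directions of the
Hessian are handled by an escalating diagonal jitter; predictions are
invariant along such directions.

**Backward elimination.** Starting from a feature set, each step
evaluates the LOOCV error of every single-feature removal and removes
the feature whose removal yields the lowest error, tie-broken by the
largest Wald p in the full-data fit. The step is accepted while the
best removal error is within **one standard error**
($\sqrt{e(1-e)/N}$) of the current error. The slack is the familiar
1-SE parsimony rule from decision-tree pruning and penalized
regression, and it is load-bearing: LOOCV error counts are integers,
and a pure-noise feature "helps" by one or two held-out cases by
chance often enough that, without the slack, roughly half of all runs
on simulated data stall with noise features still in the model. With
it, recovery of the informative subset is near-certain (measured 96 to
100% across effect sizes of 1.2 to 2 SD in the test conditions).

**Validation.** LOOCV: each case predicted by a model trained on the
other $N-1$. Two selection protocols are first-class:
`selection_mode = "inside"` repeats the elimination inside every
training fold (no selection leakage; the default) and `"pooled"`
selects once on all data and then cross-validates the fixed set — the
protocol most plausibly used when a single selected feature subset is
reported for a clinical dataset. Both are exposed so the difference is
measurable. LOOCV folds are case-wise; a patient-grouped variant is a
known limitation (see below).

**Display convention.** Percentages are *truncated* to whole percent
(93/99 = 93.94% displays as 93%), the only convention consistent with
the reference clinical report this pipeline mirrors; raw proportions
are always kept alongside. Az is the empirical trapezoidal area —
equal to the tie-corrected all-pairs Mann-Whitney statistic — rather
than a binormal maximum-likelihood fit; with ~200 cases the two differ
in the third decimal, and the empirical form is assumption-free and
exactly testable. Model comparisons use the exact McNemar binomial
test on discordant correct/incorrect pairs.

## The synthetic phantom

Clinical shoulder images cannot be redistributed, so the package
generates labelled stand-ins (`phantom_config()`,
`generate_dataset()`): an echogenicity field multiplied by smoothed
unit-mean gamma speckle, rounded to 8 bits, with a random convex
polygon ROI covering 20-60% of a 128 x 128 frame.

* **Tendinopathy**: class mean 117 with sinusoidal fibrillar bands
  (amplitude 25 gray levels, period 24 px, random orientation/phase)
  and 2-4 random hypoechoic patches — heterogeneous, relatively bright.
* **Tear**: class mean 43 with a focal hypoechoic core (level 15, 12%
  of the ROI) and a 2 px echogenic margin band (level 100) standing in
  for the adjacent tendon tissue that a delineation unavoidably
  encloses — dark, right-skewed, peaked, uniform.
* **Case-level variation**: each lesion's expected level is jittered
  around its class mean (`echogenicity_sd = 12`). Without this,
  ROI means (averages over thousands of pixels) estimate their class
  mean almost noiselessly and any mean offset separates the classes
  perfectly.
* **Speckle**: i.i.d. gamma with shape $k = 12$, Gaussian-smoothed at
  $\sigma = 1.5$ px, renormalized to frame mean exactly 1 —
  a desk-scale texture stand-in, with no claim to beamforming physics.

The class means are anchored to clinically reported median lesion
intensities (117 versus 43); the structural amplitudes were chosen once
so that the phantom reproduces the clinical *orderings* — tears darker,
more skewed, more kurtotic, higher energy, lower entropy, higher
IDN/IDM — and then frozen. Two knowing departures: tear-lesion
*variance* lands near (not below) the tendinopathy variance, and the
structural cues keep classes largely separable even at zero mean
separation, so desk-scale accuracies are optimistic. Determinism is a
contract: all randomness flows from one seed through per-case
substreams, and regeneration is bit-exact.

What phantom results show: that the implementation — geometry, feature
algebra, selection, validation, reporting — behaves correctly end to
end under known conditions. What they do not show: clinical
performance. Phantom lesions lack acoustic shadowing, anisotropy,
depth-dependent gain, probe pressure variation and true biological
texture; a desk-scale accuracy of 1.00 on phantoms is a property of
the phantom, not a clinical claim.

## Numerical and degenerate-input choices

* Rasterization: vertices are (row, col) pixel coordinates, 0-based;
  the polygon runs through pixel centers $(r+0.5, c+0.5)$; a pixel is
  inside iff its center satisfies the even-odd rule, with on-boundary
  centers counted inside (so a rectangle with corners (0,0) and (3,3)
  covers the full 4 x 4 block).
* Masked pixels are collected in row-major order — a fixed,
  reproducible order.
* `0 \log 0 = 0` in every entropy; probabilities are clamped strictly
  inside $(0,1)$ where the logistic saturates in double precision.
* Empty denominators (PPV with no positive calls), zero-variance
  moments, zero marginal SD in Correlation: `NA` sentinels, never 0.
* LOOCV folds whose training part degenerates to a single class fall
  back to the training majority and are flagged per case.
* ImageJ's binary `.roi` format is not parsed; ROIs are vertex CSVs or
  mask images, covering both plausible forms of expert delineation
  (closed polygons and freehand masks).

## Problem sizes in the shipped checks

The test suite and the acceptance script run phantom studies at 50
cases per class on 128 x 128 frames, elimination-recovery simulations
at $n = 200$ with 50 replicates, permutation calibration at 1000
replicates, and oracle comparisons (rasterization, co-occurrence
counting, texture algebra, Mann-Whitney enumeration, all-pairs Az) on
hundreds of randomized small instances — sizes chosen so the full
suite completes in minutes on a laptop while every stage is still
exercised at meaningful scale.

## Known limitations

* ROIs are inputs; no segmentation is attempted.
* Case-wise LOOCV ignores that clinical datasets contain multiple
  images per shoulder and bilateral patients; a patient-grouped
  protocol would give slightly wider (more honest) error estimates.
* The intensity features are acquisition-dependent; a classifier
  trained under one scanner setting does not transfer without
  calibration.
* Difference Variance is implemented as the variance of the gray-level
  difference distribution, the standard distinct formula; reports
  exist in the literature where its summary duplicates Contrast, which
  is consistent with $\mathrm{DV} = \mathrm{Contrast} -
  \mathrm{Dissimilarity}^2$ when dissimilarity is small.
* Binormal ROC fitting and DeLong confidence intervals for Az are out
  of scope.
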