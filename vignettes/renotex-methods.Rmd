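---
title: "Methods: synthetic CT radiomics for ccRCC grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic CT radiomics for ccRCC grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renotex)
```

## The problem

Clear cell renal cell carcinoma (ccRCC) is graded on the WHO/ISUP four-tier
nuclear scale; the dichotomy that matters for surgical planning is low grade
(I–II) versus high grade (III–IV). Pre-surgical CT offers two kinds of
evidence: *traditional* radiological characteristics a radiologist reads off
the scan (tri-axial tumor size, pre-contrast density CTpre, nephrographic
density CTpost, their difference — the enhancement), and *radiomic* texture
features computed from the pixel data of a single representative pre-contrast
axial slice. `renotex` implements the full analysis chain for combining the
two: texture extraction, reproducibility screening, and a hierarchical
stacked classifier, together with a calibrated synthetic cohort generator,
because the original patient images are not publicly deposited. Everything
downstream of the generator treats its output exactly as it would treat real
measurements.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults define the study
conditions used throughout the package.

Each phantom is a 2D axial slice: an ellipse (the tumor ROI) with random
orientation on a uniform parenchyma background of 30 HU, rendered on a
128×128 px canvas at 1 mm isotropic spacing (the resampling grid stated for
the source cohort). Patient-level characteristics are drawn from
group-conditional distributions taken from the published cohort table:

* **sizes** (transverse / anteroposterior / craniocaudal, cm) —
  log-normal, parameterized by the reported median and truncated to the
  reported min–max range. The log-SD is set so the range spans the central
  99% of the distribution, a choice that makes the truncation mild.
  Medians 4.12/4.32/4.23 (low) vs 5.98/6.02/6.30 (high).
  The craniocaudal size is metadata only (the phantom is the single axial
  slice with the largest cross-section, so the third axis never appears in
  the image). The reported size table prints "mm" but its values are
  centimeter-scale; the generator treats them as cm.
* **CTpre** (HU) — normal, 31.26 ± 7.93 (low) vs 36.41 ± 6.51 (high),
  matching the mean ± SD reporting.
* **enhancement** (HU) — log-normal by median with range truncation,
  49.66 (low) vs 38.76 (high): high-grade tumors enhance *less*.

Intratumoral heterogeneity — the texture signal — is the generator's own
calibration, not a published quantity. The pre-contrast tumor interior is
the patient's CTpre plus a stationary zero-mean Gaussian random field
(white noise smoothed by a separable Gaussian kernel, renormalized to unit
variance so the field's SD is exact everywhere, including at canvas edges).
Low-grade tumors get a smoother, weaker field (correlation length 3 px,
SD 5 HU); high-grade tumors a finer, stronger one (2 px, 8 HU) plus three
necrotic foci covering ~10% of the ROI at −25 HU. These values were chosen
once as a plausible imaging correlate of grade; with them the synthetic
classification task is clearly learnable, and indeed *easier* than the real
one (validation AUCs for the texture block are typically higher than the
published 0.80). Passing the model-ordering checks on these phantoms
therefore demonstrates that the pipeline machinery is correct, not that the
published real-data AUCs are reproduced — those depend on the unavailable
patient images.

One calibration convention deserves emphasis: after composing the texture
field and the necrosis foci, the in-mask values are recentred so the tumor's
mean attenuation equals the sampled CTpre *exactly*. The sampled CTpre is
thereby defined as the tumor's mean pre-contrast attenuation; without the
recentring, the necrosis offset would systematically shift the high-grade
group mean below its target by about 2 HU, an artifact of the rendering
order rather than a property of the modeled population.

The post-contrast image adds the sampled enhancement to solid (non-necrotic)
tumor pixels only, so `post >= pre` inside the solid tumor by construction.

What the phantoms deliberately do **not** emulate: scanner-specific noise
spectra, partial-volume and beam-hardening effects, perirenal anatomy,
contrast kinetics, and 3D shape. Results on phantoms transfer to real data
only insofar as the downstream operations are exact (feature definitions,
ANOVA, ROC arithmetic) or distribution-free.

### Cohort assembly and the 3:1 split

The default cohort is 206 low-grade and 58 high-grade patients (264 total),
each phantom seeded by a sub-seed derived deterministically from the master
seed. The training:validation split is 3:1, stratified by grade by default
(the published cohort table shows nearly identical grade proportions in both
cohorts, which stratification guarantees). Per-stratum training counts use
round-half-up: `round(0.75 × 206) = 155` and `round(0.75 × 58) = 44`, i.e.
199 training / 65 validation patients — exactly the composition the source
table prints. The unstratified variant rounds the total instead
(198/66). R's own `round()` rounds half to even, so the rule is implemented
explicitly.

### Second readers

Reader variability is emulated by `perturb_mask()`: the ROI boundary is
displaced by a smooth seeded random field scaled by a magnitude in pixels
(the new mask is `{signed boundary distance + magnitude × field > 0}`,
with the distance computed on 4-connected erosion/dilation bands). Magnitude
0 is the identity; for a fixed seed the Dice overlap with the original mask
is non-increasing in magnitude, giving a clean dial for reproducibility
experiments (default: magnitude 1 px for the intra-observer repeat, 2 px for
the second reader).

## Gray-level discretization

All texture features are computed on discretized gray levels, 256 bins by
default. The published pipeline names a vendor normalization tool but not
its formula; `renotex` uses the standard μ ± 3σ windowing: the in-mask mean
and (population) SD define the window, values are clipped to it and mapped
linearly to integer levels 1..256 (half-open bins, top edge closed). The
window multiplier is configurable. Two consequences worth knowing:

* discretization is invariant to affine rescaling of the in-mask
  intensities — deliberate, since its purpose is harmonizing scanners — so
  first-order *level* statistics carry almost no CTpre information; the
  mean-density signal lives in the traditional block;
* a constant ROI (σ = 0) maps every pixel to the mid level 128 instead of
  erroring, keeping degenerate inputs processable.

## The 340-feature registry

The published total is 340 texture features from six families; the exact
manifest of the vendor tool is not recoverable, so the registry pins a
documented composition that reaches the printed total and is auditable
feature by feature:

| family | count | composition |
|---|---|---|
| histogram | 11 | mean, variance, skewness, kurtosis, percentiles 1/10/25/50/75/90/99 |
| gradient | 5 | moments of the central-difference magnitude + nonzero fraction |
| autoregressive | 5 | θ₁..θ₄ of the 4-neighbor causal model + residual SD |
| co-occurrence | 275 | 11 Haralick features × (4 directions × 5 distances + 5 direction-averaged) |
| run-length | 20 | SRE, LRE, GLN, RLN, fraction × 4 directions |
| wavelet | 24 | Haar subband energies LL/LH/HL/HH × 6 scales |

Conventions, fixed once and used everywhere: population moments; nearest-rank
percentiles; log₂ entropies with 0·log 0 ≡ 0; symmetric co-occurrence
accumulation normalized to sum 1; co-occurrence correlation defined as 0 when
a marginal variance vanishes; directions in image coordinates (0° = +column,
90° = +row); run-length runs confined to in-mask collinear segments (the
mask boundary breaks a run); the AR model is fitted by least squares on
mean-centered levels with a tiny-ridge fallback (`1e-8`, trace-scaled) for
rank-deficient designs; the wavelet patch is the mask bounding box filled
with the in-mask mean and padded to a square power of two of at least 64 so
all six scales are feasible.

Cells that are structurally infeasible — a co-occurrence displacement with
no in-mask pixel pair, a wavelet scale deeper than the patch — emit the
sentinel value 0 together with a `FALSE` validity flag, so the feature
vector length is stable for modeling and nothing fails silently. The default
registry ships as a JSON manifest (`inst/extdata/registry_340.json`) and a
test asserts it matches the in-code definition.

Every family is checked against an independent brute-force implementation
(explicit double loops over pixels and matrix entries) on randomized small
images, at tolerance 1e-10 or tighter.

One identifiability note on the AR family: because the fit has no intercept
*after* mean-centering, a field synthesized by an exact causal recursion
whose coefficients do not sum to 1 acquires a constant offset in the
centered equations, and the recovered θ is biased by that offset. The
parameter-recovery test therefore synthesizes with θ summing to 1, for which
centering is exact and recovery is at machine precision.

## Reproducibility screening

Reader agreement uses ICC(2,1) — two-way random effects, absolute agreement,
single measurement — computed from the ANOVA decomposition. The model choice
is the package's own (the source protocol does not name one); ICC(3,1)
(consistency) is available via an argument, and the identical-columns /
constant-offset behaviors that distinguish the two are tested. Qualitative
bands follow the published cutpoints (poor < 0.21, fair to 0.40, moderate to
0.60, good to 0.80, excellent above), with the unassigned sliver
[0.20, 0.21) resolved to poor; ICC > 0.75 is flagged as "good agreement".
Matrices with zero total variance return ICC 1, flagged as degenerate.

`reproducibility_report()` computes per-feature intra-observer (Reader 1
twice) and inter-observer (Reader 1 vs Reader 2) ICCs. Mirroring the source
protocol, Reader 1's first-pass features are always the analysis set; an
optional retention filter (e.g. ICC > 0.75 on both axes) is off by default
because the source text keeps all Reader-1 features.

## The stacked classifier

Each feature block (texture; traditional) is fused in two stages:

1. **LASSO** (`glmnet`, binomial, α = 1): lambda chosen by seeded stratified
   10-fold CV at minimum deviance (a 1-SE rule is available). The linear
   predictor is the block's signature score — the "Rad-score" for the
   texture block. If the chosen lambda selects nothing, the
   minimum-deviance lambda is the fallback; an empty selection yields a
   constant intercept score, which the downstream SVM then drops as a
   degenerate input.
2. **Random forest** (500 trees, seeded) on the LASSO-selected features —
   the published recipe reuses the selected set.
3. A **linear SVM** fuses the two scores per block (SVM1 for texture, SVM2
   for traditional), and a second-level linear SVM (SVM3) fuses the two
   block SVM scores into the final score.

Decisions the source leaves open, and how they are fixed here:

* **Stacking inputs.** By default the training-row scores fed to the SVMs
  are cross-fitted (5-fold refits at the chosen lambda for the LASSO score,
  out-of-bag votes for the forest), preventing the optimism that in-sample
  stacking inputs would leak into the fusion. `naive_stacking = TRUE`
  reproduces the literal in-sample recipe; both modes are tested.
* **SVM scores.** The continuous score is the decision value, with its sign
  oriented once from the training class means so that larger always means
  high grade. Decision values (rather than Platt probabilities) keep the
  model fully deterministic under a fixed seed: the underlying library's
  probability calibration has its own unseeded randomness.
* **Kernel, trees, folds.** Linear kernels (the fused spaces are 1–2
  dimensional), 500 trees, 10-fold CV — all in `stack_config()`.
* **Binarization.** The threshold on the final score is the Youden-optimal
  point of the training ROC (ties toward the lower threshold; calls use the
  ≥ convention). The source states that scores are binarized but not how.

All fitted statistics — standardization parameters, lambda, forest, SVMs,
threshold — derive from training rows only; a test refits after withholding
validation rows entirely and asserts identical validation predictions.

## Evaluation

AUC is the Mann–Whitney pairwise statistic (ties ½), computed from
mid-ranks and verified against an all-pairs enumeration oracle. ROC curves
are threshold sweeps over the observed scores. Confidence intervals:
stratified bootstrap percentile by default (cases and controls resampled
separately, so no resample is degenerate), DeLong's placement-value interval
as the fast alternative. Coverage of the nominal 95% bootstrap interval is
checked by simulation (500 replicates at n = 200, true AUC 0.8, binormal
scores) and falls in the 0.93–0.97 band.

Threshold metrics report both the textbook FNR = FN/(TP+FN) and
FPR = FP/(TN+FP) *and* whole-cohort variants FN/n and FP/n
(`fnr_cohort`/`fpr_cohort`): published tables in this literature sometimes
use the whole-cohort denominator, and the two should not be conflated.
Orientation is never flipped silently — an AUC below 0.5 produces a warning
only.

Group comparisons dispatch Pearson's chi-square without continuity
correction for categorical variables, Welch's t for continuous variables
declared normal, and the Wilcoxon rank-sum (normal approximation with tie
correction; exact enumeration available for small untied samples) otherwise.
Feature correlation uses Spearman by default, reporting magnitudes alongside
signed values, with zero-variance features flagged and set to 0.

## Pipeline and problem sizes

`run_end_to_end()` chains simulate → extract → reliability → train →
evaluate with plain-file handoff (CSV/JSON) and a checksum manifest; a stage
refuses to run if an upstream file changed, and a run is byte-identical
under a fixed config and seed.

Problem sizes used by the test suite, chosen so the full suite exercises the
default study conditions where the claim depends on them and compact
conditions elsewhere: unit tests run on 64 px phantoms with 2–4 cm tumors;
calibration checks use 500 phantoms per grade at full size; the
model-ordering property runs the complete 264-patient pipeline over 20
seeds; LASSO recovery uses 45-patient cohorts over 20 seeds against an
informative-feature set defined by effect sizes (> 0.8 pooled-SD units) on
an independent 180-patient reference cohort; bootstrap coverage uses 500
simulations with 500 resamples each.

## Known limitations

* The 340-feature manifest is a documented reconstruction of the vendor
  tool's composition, not a bit-exact reproduction of its outputs.
* Phantoms are statistically calibrated to the published cohort's
  *traditional* characteristics only; texture separability is an assumption,
  set once, and is stronger than the real data's.
* The published real-data AUCs (0.92 training / 0.91 validation for the
  combined model) are not reproducible targets without the patient images;
  the package reproduces the structural and statistical properties of the
  method instead.
* Size distributions are sampled independently per axis; real tumor axes
  are correlated.
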