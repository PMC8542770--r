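---
title: "Methods: fetal brain age from multiplanar MRI slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fetal brain age from multiplanar MRI slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

Fetal brain structure changes rapidly and consistently with gestational age
(GA): brain volume grows, the cortical ribbon folds, and the ventricles wane
in relative prominence after mid-gestation. `fetalage` predicts GA ("brain
age", in weeks) directly from the thick-slice T2-weighted stacks that are
acquired clinically in several orthogonal planes, without inter-slice motion
correction, tissue segmentation, or surface reconstruction.

The method has three ingredients:

1. **A 2D single-channel residual regression CNN.** Every sufficiently
   central slice of every stack is treated as an independent sample. The
   trunk is a pre-activation residual network (batch normalization → ReLU →
   convolution inside each block) that downsamples the canonical input
   32-fold per axis (a 138 × 176 slice reaches a 5 × 6 feature map),
   followed by global average pooling, dropout (rate 0.3), and a single
   linear output. Working per-slice sidesteps inter-slice motion entirely
   and multiplies the effective sample size.
2. **Test-time augmentation (TTA).** Each slice is predicted under `n_tta`
   random draws of the shared augmentation family (vertical/horizontal
   flips, ±20% translations, 0-360° rotation, intensity gain 0.5-1.0) and
   the predictions are averaged:
   `p_tta = (1 / n_tta) * sum_t p_t`. This removes the arbitrary
   orientation/position of the fetal head from the prediction. The default
   `n_tta = 20` sits at the point where the slice-level MAE stops improving
   in the `sweep_tta()` diagnostic.
3. **Grouped-mode aggregation.** A subject's many per-slice predictions are
   collapsed with the grouped (class-interval) mode
   `M = L + i (f1 - f0) / (2 f1 - f0 - f2)`, computed on a histogram of
   width `i = 0.2` weeks. The mode ignores minority outliers (predictions
   from motion-corrupted or low-signal slices) that still bias the mean,
   and, unlike the median, uses sub-bin interpolation. The predicted age
   difference is `PAD = GA - brain age`, and the cohort error is the MAE of
   absolute PADs.

## Numerical conventions that affect results

* **Histogram anchoring.** The grouped-mode value depends on where bin
  edges sit. Bins are half-open, `[k*i, (k+1)*i)`, anchored at zero. A
  representation-error nudge (`floor(v / i + 1e-8)`) keeps values such as
  30.0 in the bin whose lower edge they define. Identical values
  `rep(30, 7)` at `i = 0.2` therefore give `M = 30.1` — the worked example
  in the unit tests pins this convention.
* **Ties and degeneracies.** Two or more tied modal classes fall back to
  `3*median - 2*mean`. A vanishing interpolation denominator
  (`2 f1 = f0 + f2`, only possible adjacent to a tie) returns the
  modal-class midpoint `L + i/2` with a logged message.
* **Strict empirical p-values.** The random-selection test draws one slice
  (or stack) per subject, 10,000 times, and reports
  `p = #{null < reference} / n_rep`; ties count against rejection, and
  `p * n_rep` is always an integer.
* **SD conventions.** Sample SD everywhere; a single subject reports SD 0.
* **Early stopping** keeps the weights of the epoch with the best
  validation MAE and halts once no improvement has been seen for
  `patience` epochs.
* **"Center of the brain"** for slice selection is the mask-area-weighted
  centroid of slice positions along the stack normal; ties in the distance
  ranking resolve toward the lower slice index. The four nearest usable
  slices per stack feed training and stack-wise evaluation.
* **Cropping is per stack**, not per slice: one bounding box (the union of
  the stack's usable masks after 1 mm resampling) keeps within-stack slice
  geometry consistent.
* **Intensity normalization** divides each slice by the 99th-percentile
  masked intensity and clips to [0, 1.5]; the augmentation family's
  intensity gain (0.5-1.0) presumes inputs on a bounded scale.

## Preprocessing chain

`preprocess_stack()` runs masking → bias correction → denoising →
resample/crop/pad:

* **Masking** is pluggable (`masker` argument accepts any slice → mask
  callable; clinical pipelines would plug a learned segmenter here). The
  default is Otsu thresholding + largest connected component + hole fill.
  Slices whose mask is tiny relative to the stack's largest, or whose
  masked median intensity is far below the brain slices' (a threshold
  masker on a brain-free slice segments the upper noise tail), are flagged
  unusable rather than failing.
* **Bias correction** is a homomorphic fit: a second-order 2D polynomial
  fitted to the log intensity of dominant-tissue pixels (mask eroded to
  drop partial-volume edges, then restricted to ±15% of the median), shared
  across the stack and normalized to unit mean in the mask. Fitting only
  one tissue class keeps anatomy out of the field, so a bias-free stack
  passes through unchanged; its contract (within-rim coefficient of
  variation decreases) is tested on phantoms with a known applied field.
* **Denoising** is a windowed non-local means (3 × 3 patches, 5 × 5 search
  window, noise-compensated exponential kernel with bandwidth
  `1.2 × sigma`, calibrated once on phantoms to halve flat-region noise
  while keeping re-masking Dice ≥ 0.99). The noise SD is estimated from
  the median absolute Laplacian pseudo-residual, which is exactly zero on
  a noise-free structured image — so the filter is the identity there.

## The phantom generator

Because clinical fetal MRI cannot ship with a package, every stage is
exercised on synthetic phantoms (`phantom_params()`, `generate_volume()`,
`acquire_stack()`, `generate_cohort()`). The phantom encodes the three GA
cues the method is expected to exploit, each carrying independent
information:

* **Size**: a bright ellipsoid with mean major semi-axis
  `11 + 0.55 (GA - 16)` mm — a deliberate desk-scale stand-in, roughly half
  the anatomical growth curve so that late-gestation brains still fit a
  64 × 64 1-mm canonical frame; it is *not* a biological growth model.
* **Folding**: the cortical rim (2.5 mm shell, mean intensity 1.0 vs 0.7
  parenchyma) is radially perturbed by
  `fold_amplitude * sin(fold_frequency * θ)` patterns whose amplitude
  (0.08 mm/week) and frequency (0.35/week) grow with GA, and the ribbon's
  intensity is textured by the same angular pattern (amplitude
  `0.25 tanh(fold_amplitude)`, so it vanishes in the fold-free degenerate
  case). The texture makes folding complexity an in-plane image cue, as
  sulcation is in real fetal MRI, rather than only a boundary wiggle.
* **Ventricles**: paired dark (0.35) interior ellipsoids whose relative
  scale peaks at 22 weeks (0.45) and declines afterwards (0.012/week).

Acquisition then mimics the clinical protocol: slab averaging into 3 mm
slices at 1.5 mm in-plane spacing, independent per-slice rigid jitter
(SD 0.5 mm, 1°), a smooth random low-order multiplicative bias field
(peak-to-trough 0.2), and additive Gaussian noise (SD 0.05 against a 0-1
tissue scale). Gaussian noise is a simplification (magnitude MRI noise is
Rician); the generator takes `noise_sigma` and all corruption strengths as
parameters, and with all of them zero `acquire_stack()` is an exact slab
average, which the tests verify against direct averaging.

What the phantom does **not** emulate: real anatomy (gyral geometry,
tissue-contrast changes with maturation), maternal tissue around the brain
(stacks arrive pre-cropped), through-plane motion, coil/physics effects.
Passing tests on phantoms therefore demonstrates that the machinery is
correct and that the model can discover size/folding/ventricle cues — not
clinical-grade accuracy.

## Training harness

* Folds and validation splits are **by subject**, never by slice, and
  stratified over the nine cohort age groups (under 23 weeks pooled, then
  2-week periods to 39). Oversampling duplicates *subjects* until bin
  occupancy is near uniform (max/min ≤ 1.25).
* Loss is Huber with δ = 1.0 week; the output bias is initialized at the
  training-set mean age so the bounded-gradient loss does not spend epochs
  walking the output into the data range.
* The `paper` configuration profile records the full-scale hyperparameters
  (batch 80, Adam at learning rate 0.1 with decay 0.001, patience 150, the
  101-layer bottleneck trunk). "Decay" is implemented as inverse-time decay
  `lr / (1 + decay * step)` — the conventional reading of that optimizer
  option — without asserting that is the original intent. The `desk`
  profile (batch 32, Adam 1e-3, small residual stack, patience 8) exists
  because learning rate 0.1 with Adam is unstable at small batch sizes and
  the package must train on one CPU; the full profile is kept as a
  configuration surface, not an accuracy claim.
* The 2D multi-channel variant feeds the four selected slices as input
  channels; the volumetric variant stacks them as a depth axis with 3D
  convolutions. Both predict one age per stack and share the training
  strategy; their augmentation uses the same in-plane family applied
  identically to every slice of a sample, avoiding through-plane
  interpolation across thick slices.

## Problem sizes and determinism

The shipped end-to-end study (`desk_experiment()`, also what
`scripts/acceptance.R` runs) simulates 120 training and 15 held-out
subjects, three orthogonal stacks each, 64³ voxels at 1.5 mm, trains the
single-channel and volumetric arms for up to 15 epochs (patience 5), and
evaluates with 20-fold TTA; these sizes are the package's chosen desk
scale. Every stage draws from a stream derived from one master seed (per
subject, stack, slice, fold, and TTA run), so cohorts, fits and every
reported number are reproducible bit-for-bit; re-running any piece with the
same seed is asserted identical in the tests.

## What the desk-scale probes do and do not show

The phantom study demonstrates mechanism, not clinical ordering, and two of
its probes are honest negatives under the shipped conditions:

* **Saliency localization.** The trained model's gradient maps reliably
  elevate the ventricles, but the *mean* over the combined rim + ventricle
  region does not exceed the remaining interior: with a global-average-
  pooling head, the area-counting features that read brain size assign
  input gradient almost uniformly over the interior, so interior saliency
  is genuine signal in a size-dominated phantom. Clinical images, whose
  cortical structure dominates, are a different regime.
* **Architecture ordering.** On clinical data the per-slice single-channel
  model outperforms the volumetric model stack-wise; the mechanisms are
  inter-slice motion and the dimensionality/sample-size penalty. Under the
  phantom's conservative motion jitter (SD 0.5 mm, 1°; clinical fetal
  motion is typically several mm) and clean geometry, the volumetric arm
  sees an easier problem and wins the desk comparison. The jitter default
  was fixed before any comparison was run and deliberately left untouched
  afterwards; the comparison harness itself (paired stack-wise Wilcoxon) is
  exercised either way.
* Likewise, the mode-beats-mean ordering needs outlier-contaminated
  predictions (it holds on the contaminated simulated cohort); the phantom
  cohort's mild corruption produces roughly symmetric per-slice errors, and
  there the mean aggregate is the better estimator, as theory predicts.

## Known limitations

* The phantom's GA-to-geometry mapping is invented; absolute MAEs on
  phantoms say nothing about clinical MAEs.
* The CNN engine is a compact pure-R implementation (BLAS-backed im2col);
  it is exact (finite-difference-verified gradients) but not fast — the
  paper-profile network builds but is not trainable in reasonable time
  without accelerators.
* The default masker is threshold-based and assumes the brain is the
  brightest large structure; real pipelines should plug a learned masker
  into the `masker` seam.
* Slice positions assume a regular slice grid per stack; irregular
  acquisitions are not modeled.
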