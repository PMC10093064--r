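---
title: "Foreground-prototype one-shot segmentation: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foreground-prototype one-shot segmentation: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Supervised tumor segmentation networks need hundreds of annotated scans and
generalize poorly to unseen classes. `protoseg` implements the alternative of
episodic few-shot segmentation with a *single foreground prototype*: in every
episode a *support* set of annotated slices and a *query* slice (or scan) pass
through a shared convolutional encoder $f_\theta$; the support features are
condensed into one prototype and the query is segmented by similarity to it.
No background prototype is ever computed — the overwhelming healthy-tissue
class is handled purely through the loss weighting, which avoids over-training
on background.

The pieces, in the order they execute:

1. **Masked average pooling (MAP).** With support features
   $\chi^s(i,j) \in \mathbb{R}^{256}$ and the binary foreground mask
   $\eta(i,j)$ at feature resolution, the prototype is
   $\rho = \sum_{i,j} \chi^s(i,j)\,\eta(i,j) \big/ \sum_{i,j} \eta(i,j)$.
   For C-shot K-way support sets the mean runs over the foreground locations
   of all $C\cdot K$ slices pooled together. MAP is undefined (an error) for
   an empty mask.

2. **Scaled negative-cosine scoring.** Every query feature vector is scored
   against the prototype with
   $R(i,j) = -\alpha \cos\!\big(\chi^q(i,j), \rho\big)$, $\alpha = 20$.
   This is an anomaly-style score: perfect congruence gives $-\alpha$,
   incongruence $+\alpha$. The scaling sharpens the sigmoid that follows;
   cosine similarity makes the score invariant to positive rescaling of
   features. Zero feature vectors (zero padding) receive score 0 rather than
   an exception.

3. **Soft thresholding.** Scores become foreground probabilities via
   $M(i,j) = 1 - \sigma\!\big(R(i,j) - \beta\big)$ with a single *learned*
   scalar $\beta$. $M = 0.5$ exactly where $R = \beta$, which is also the
   binarization pivot at inference. $\beta$ is initialized at
   $-\alpha/2 = -10$, the midpoint between the perfect-match score $-20$ and
   the orthogonal score $0$; it trains jointly with the encoder.

4. **Losses.** The segmentation loss is a class-weighted binary cross-entropy
   averaged over pixels, weight 1.0 on tumor and 0.2 on background (the
   imbalance control). The prototype alignment regularizer (PAR) reverses the
   roles: the predicted query mask, binarized at 0.5, selects query features
   whose MAP becomes a query-derived prototype $p_c^q$; the support slices
   are then segmented against it and scored with the same weighted
   cross-entropy against the support ground truth. The total loss is
   $L = L_{seg} + \lambda L_{PAR}$ with $\lambda = 1$.

5. **Training.** SGD with momentum 0.9, batch size one episode, learning rate
   $10^{-3}$ decayed by 0.97 every 1000 iterations, and L2 weight decay
   $5\times10^{-4}$ on convolution weights (not biases or $\beta$). Training
   episodes pair one query slice with support slices from the *same* case but
   different slice indices, all containing foreground.

6. **Inference.** One annotated slice from the middle of the support volume
   (deterministically: the median foreground-bearing slice; optionally a
   seeded draw from the middle third) yields the prototype; *every* slice of
   the query scan is scored against it, upsampled to mask resolution,
   soft-thresholded, and binarized at 0.5. Metrics — Dice
   $2|X\cap Y|/(|X|+|Y|)$, IoU, precision — are computed with integer pixel
   counts pooled in 3-D per scan, then aggregated over cases and k-fold
   splits (mean, sd, max).

## The encoder

The published description of the backbone is internally contradictory
(a VGG-16 architecture carrying ResNet-101 weights), and no pretrained
weights are downloadable in an offline build. The package therefore treats
the encoder as a pluggable component behind a fixed contract — 3-channel
input, 256 output channels, spatial stride 8 — and ships a compact
randomly-initialized default: three stride-2 $3\times3$ convolutions
(16, 32, 64 channels, ReLU, He initialization) followed by a linear
$1\times1$ projection to 256 channels. Biases are initialized uniformly in
$\pm 0.1$: with zero biases a ReLU network is positively homogeneous, so
cosine scores could never separate classes that differ mainly in intensity
scale. The forward and backward passes are written directly in R (im2col
gathers feeding BLAS matrix products); gradients are verified against finite
differences in the test suite. Every batch-shape consequence of the contract
holds, e.g. a 1-shot 1-way episode with a standard 21-slice query stack
encodes to $(22, 256, 32, 32)$ for $256\times256$ inputs.

## Preprocessing pipeline and its parameters

Fixed order: intensity clipping → slice resampling → ROI crop →
label binarization → standardization. The published account mentions both
cropping and resizing without ordering them; cropping first keeps the resize
target fixed at $256\times256$.

* **Clipping** removes the top 0.5% of intensities (off-resonance bright
  spots), replacing them by the inverse-CDF 99.5th-percentile value — an
  observed voxel value, which makes the operation exactly idempotent.
* **Slice resampling** to exactly 21 slices (linear interpolation for
  intensities, nearest neighbour for labels so the label set
  $\{0,1,2,4\}$ is closed under resampling). "Around 20" is fixed to 21 so
  that the support+query encoder batch is $C\cdot K + 21$, consistent with
  all six published batch shapes (22, 26, 26, 31, 46, 71).
* **ROI crop**: in-plane bounding box of the nonzero labels over all slices,
  expanded by an 8-voxel margin (unstated in the source; chosen small) and
  clamped to the grid. All slices are kept.
* **Binarization** merges labels 1, 2, 4 (necrotic core, edema, enhancing
  tumor) into one whole-tumor class.
* **Standardization**: bilinear resize of each slice to $256\times256$,
  min-max normalization to $[0,1]$, channel replicated three times.
  Normalization is **per volume**, not per slice. This is a deliberate
  design choice: whole-scan inference compares every slice with one support
  prototype, and per-slice rescaling stretches tumor-free slices to the full
  intensity range, making healthy tissue numerically indistinguishable from
  tumor. In internal experiments per-slice normalization collapsed
  volume-level Dice to ≈0.2 while tumor-bearing slices scored ≈0.96;
  per-volume normalization (the standard MRI convention) preserves
  inter-slice contrast and restores volume-level performance. A constant
  volume normalizes to zeros.
* **Augmentation** (training only, optional): per slice with probability
  0.5, one random affine transform — rotation within ±15°, translation
  within ±10 px, shear within ±10° — applied identically to image and mask,
  mask re-binarized; slices are replaced, not duplicated. Bounds are mild
  because the source does not quantify them.

All resampling is built on explicit 1-D linear-interpolation operators; the
same operator matrices act as exact adjoints during backpropagation, which is
why the bilinear upsampling of score maps is expressible inside the training
gradient.

## What the synthetic generator emulates — and what it does not

Each case is a $96\times96\times150$ volume: an ellipsoidal "brain" of tissue
(intensity 100 ± 20 with a smooth per-case gradient and voxel noise sd 10) on
a dark surround, containing one axis-aligned ellipsoidal "tumor" with
jittered centre, per-axis radii drawn from 8–18% of each dimension, and
intensity 300 ± 30 rising towards the core. Labels are nested shells —
enhancing (4) innermost, edema (2) outermost — exercising the class-merging
rule. The in-plane grid is kept at 96 voxels (downscaled from the
240-voxel clinical grids) because the preprocessing chain rescales to
$256\times256$ anyway; 150 slices match the typical clinical slice count.
The tumor/tissue contrast is deliberately separable: these volumes validate
the machinery (episodes, pooling, scoring, losses, inference protocol), not
clinical difficulty. They do not emulate MRI physics, bias fields,
multi-modality, infiltrative margins, multifocal tumors, or
tumors isointense with tissue — so passing end-to-end tests demonstrates
correct mechanics and learnability on separable data, not clinical-grade
accuracy.

## Numerical choices and degenerate inputs

* Cross-entropy probabilities are clamped to $[10^{-7}, 1-10^{-7}]$;
  gradients are taken in score space, which needs no clamping.
* Cosines are clamped to $[-1, 1]$ against floating-point overshoot.
* PAR with an empty binarized query mask contributes 0 (MAP would be
  undefined; early training would otherwise crash).
* An episode whose support masks vanish after downsampling to the feature
  grid is resampled.
* Ties and draws: slice sampling is uniform without replacement over
  foreground-bearing slices; the deterministic support-slice rule takes
  element $\lceil n/2 \rceil$ of the sorted foreground slice indices.
* "Ways" after class merging: K-way sampling draws K additional support
  slices per shot, all mapped to the single merged class — consistent with
  the published shape table, where 1-shot 5-way and 5-shot 1-way produce the
  same batch shape.
* Learning-rate "per 1000 epochs" decay is applied per 1000 iterations; the
  source uses the two terms interchangeably and only iteration counts are
  actionable.

## Desk-scale problem sizes

The test-suite and the worked examples run on reduced sizes chosen as the
package's own defaults for a single CPU: unit tests use $32\times32$ toy
stacks with a narrow (8, 16, 32)-channel encoder; the end-to-end training
check uses 20 training and 6 held-out synthetic cases at the full
$256\times256$ pipeline resolution with 1500 training iterations (the
full-scale published schedule is 50,000). The 5-fold cross-validation
harness is exercised at toy scale.

## Known limitations

* The ROI crop is label-dependent (as published), so inference presumes an
  annotated support scan *and* a crop around the query's own labels; this
  leaks the query bounding box and inflates absolute scores — a property of
  the protocol being reproduced, not a bug. Very small tumors produce tight
  crops and strong upsampling, which can make smooth tissue mimic tumor
  texture on tumor-free slices of the same scan; this is the dominant
  residual error mode on synthetic cases.
* One prototype models one coherent foreground; multifocal tumors with
  distinct appearance would need multi-prototype clustering, which is out of
  scope.
* The compact default encoder is not pretrained; published full-scale scores
  on clinical data (Dice ≈ 83 on BraTS-2021) require the clinical dataset
  and a GPU-scale backbone and are expressly not reproduced here.
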