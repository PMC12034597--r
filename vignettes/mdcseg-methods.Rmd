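---
title: "Two-step semi-supervised segmentation with multi-dimensional consistency: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step semi-supervised segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Voxel-level annotation of tubular anatomy — the intestine in abdominal CT is
the motivating case — is so expensive that a typical cohort has a handful of
densely annotated volumes, a larger number of volumes annotated on a few
scattered axial slices, and many volumes with no labels at all. A purely 3D
network trained on the few labeled volumes underfits; a purely 2D network
sees far more training samples (every axial slice is one) but ignores
through-plane context. `mdcseg` implements a two-step semi-supervised
pipeline that combines the two:

1. **Step 1** trains a 2D slice network on the axial slices of the labeled
   volumes.
2. The frozen step-1 network predicts every slice of every unlabeled patch;
   the per-slice probability maps are merged back into a patch and
   discretised by argmax. These **pseudo-labels** are written to disk and
   never revisited.
3. **Step 2** trains a 3D patch network on labeled patches (against ground
   truth) and unlabeled patches (against their pseudo-labels).

The cross-dimensional supervision is the point: the 3D network is pushed to
be consistent with a 2D view that was itself trained on many more samples.

## Losses

With per-voxel softmax probabilities $p$ and binary targets $t$, the
supervised loss on labeled data is the weighted compound

$$L_{sup} = \alpha\, L_{ce} + (1-\alpha)\, L_{dice}, \qquad \alpha = 0.3,$$

where $L_{ce}$ is mean cross-entropy and $L_{dice}$ is soft Dice on the
foreground class,

$$L_{dice} = 1 - \frac{2\sum p_1 t_1 + s}{\sum p_1 + \sum t_1 + s},$$

with smoothing $s = 10^{-5}$. The unsupervised loss on pseudo-labeled
patches is Dice alone — cross-entropy against pseudo-labels is unstable
under the severe class imbalance of thin tubular foreground, while
foreground Dice is insensitive to the overwhelming background mass. The
total step-2 loss is the unweighted sum

$$L_{total} = L_{sup} + L_{un}.$$

Numerical conventions, all exercised by the test suite:

* probabilities are floored at $10^{-12}$ before any log;
* soft Dice is computed **per batch item and then averaged**, not pooled
  over the batch — with unequal foreground sizes the two differ, and the
  per-item form keeps small-foreground patches influential;
* an empty target with an empty prediction has Dice loss exactly 0
  (the ratio degenerates to $s/s$);
* no ramp-up schedule is applied to $L_{un}$: the total is a plain sum,
  and pseudo-labels are integer constants, so no gradient can reach the
  2D network through the consistency term (asserted in the tests);
* all pseudo-labeled voxels enter $L_{un}$; no confidence thresholding.

## Networks

No deep-learning framework is assumed: both networks are implemented in
the package, forward and backward, over BLAS matrix products (the
convolution hot path is compiled C++), and every backward pass is verified
against central finite differences in the test suite.

* **2D slice network** (`net2d_config()`): a U-shaped encoder–decoder on
  axial slices with a convolutional stem and, at the 1/2 and 1/4
  resolution stages, windowed single-head self-attention blocks
  (pre-LayerNorm, residual) over non-overlapping `window x window` token
  tiles — hierarchical windowed attention for long-range in-plane context,
  convolutions for local mixing. Decoder stages compress skip
  concatenations with a 1x1 convolution before the 3x3 convolution.
* **3D patch network** (`net3d_config()`): a plain 3D convolutional U-Net
  with `n_levels` resolutions, one 3x3x3 convolution per encoder level
  (two at the bottleneck), 2x mean-pool / nearest-upsample transitions,
  and the same compress-then-convolve decoder.

The tiny presets (2D: `embed_dim = 24`, `window = 4`, input 32x32; 3D:
`base_channels = 8`, `n_levels = 3`, input 32x32x8) train a meaningful
single-sample overfit in under two minutes on one CPU; both reach
foreground Dice above 0.95 on one clean phantom example, which is the
trainability bar the tests enforce. Clinical-scale inputs
(256x256x16 windows) are a configuration change, not a code change.

Output probabilities come from a softmax over the class axis; argmax (ties
broken toward background, so an exact 0.5/0.5 voxel is background) is
applied only when generating pseudo-labels or final segmentations, never
inside a loss. The 2D network is randomly initialised; no pretrained
weights are used.

## Patching and stitching

Sliding-window patches use the lattice `{1, 1+s, 1+2s, ...}` per axis plus
one clamped origin at `dim - w + 1` whenever the lattice does not already
end there, so every voxel is covered without synthetic padding; volumes
smaller than the window are zero-padded at the high end. Patch enumeration
order is fixed (z slowest, then y, then x), which makes pseudo-label caches
reproducible. Overlapping patch predictions are fused by the arithmetic
mean of probabilities *before* argmax — the variance-reducing choice — and
renormalised per voxel. All indices are 1-based, the native R convention.

## Synthetic phantoms

The generator (`phantom_spec()`, `make_phantom()`, `make_cohort()`)
emulates the *structure* of the clinical cohort, not CT physics:

* tubular foreground: smoothed random-walk centerlines dilated with a
  Euclidean ball of sampled radius (3–5 voxels by default), mimicking
  folded bowel curvature;
* confounders: ellipsoids with intensity drawn within ±10% of the tube
  intensity but labeled background, the first placed touching a tube —
  an intensity threshold cannot separate them, shape context can;
* class imbalance: geometry is redrawn until the foreground fraction lies
  in a configurable band (1–15% by default);
* annotation structure: dense masks, sparse masks on a uniformly sampled
  5% of slices (the clinical range is a few percent), and unlabeled cases,
  with per-case seeds split deterministically from one master seed;
* defaults are noise-free and high-contrast (tube intensity 1 on
  background 0), the regime the package's end-to-end claims are made in;
  `noise_sd` adds Gaussian intensity noise without touching labels.

What phantoms do **not** model: HU calibration, partial-volume and beam
artifacts, peristalsis, air–fluid levels, neighbouring-organ texture.
Passing the end-to-end tests therefore demonstrates that the pipeline's
machinery (pseudo-labeling, consistency training, stitching, sparse-slice
evaluation) works and that the consistency term helps when labels are
scarce — it does not certify clinical accuracy.

## Training procedure

SGD with momentum 0.9 (no weight decay) under the poly schedule
`lr = lr0 (1 - epoch/max_epochs)^0.9` with `lr0 = 0.01`; the schedule is
driven by epochs. Checkpoint selection keeps the weights with the best
validation Dice — computed on stitched volumes under the same
labeled-slices-only rule as testing, every `val_every` epochs for speed —
and training stops early exactly `patience` epochs after the last
improvement, never exceeding `max_epochs` (500 by default). The untrained
model is validated once before epoch 1 so a diverging run can never beat
the initialisation silently.

Augmentation: random axis flips applied identically to image and labels
(2D and 3D); 3D cut-out zeroes one random box, about 10% of the patch
volume, in the *image only*. Step-2 batches pair one labeled and one
equal-sized unlabeled batch per optimization step (the sampling ratio is
not dictated by the loss, which weights the two terms equally).

## Desk-scale study conditions

The package's own experiments (`desk_config()`, the acceptance script, the
heavier tests) run on a cohort of 2 labeled + 6 unlabeled training
volumes, 2 validation and 4 test volumes of 64x64x32 voxels, with
32x32x8 windows and 16x16x4 stride; training runs 8 epochs of 12 steps at
batch size 4 with validation every 4 epochs, three training seeds per arm.
These sizes were fixed once, from a single-seed pilot, as the smallest
configuration at which both arms converge on high-contrast phantoms in a
few minutes on one CPU; per-case Dice is averaged over seeds, summarised
as mean ± SD over cases, and the two arms are compared with the paired
two-sided Wilcoxon signed-rank test.

## Evaluation conventions

Dice, precision and recall are counted on the foreground class over the
**labeled slices only** — corrupting predictions anywhere else provably
changes nothing (a test flips every unlabeled slice and asserts bit-equal
metrics). When ground truth and prediction are both empty all three
metrics are 1 (a sparse slice can legitimately contain no foreground); an
empty denominator against a non-empty counterpart gives 0.

The Wilcoxon signed-rank test drops zero differences, enumerates all
$2^n$ sign assignments (tie-averaged ranks) exactly for $n \le 12$, and
uses the normal approximation with tie correction otherwise; if every
difference is zero the comparison is degenerate and $p = 1$ by
convention.

## Known limitations

* Phantoms are geometric stand-ins; no claim transfers to clinical CT
  without retraining and revalidation.
* The slice network processes slices patch-wise (as the pipeline's data
  flow depicts); with the clamped-lattice edge policy this tiles the
  plane exactly, but probabilities near lateral patch borders still come
  from restricted context.
* Single-head attention and the slim decoders are capacity choices made
  for CPU-scale training; at clinical scale wider variants may be
  preferable (all widths are configuration).
* Pseudo-labels are generated once and frozen; no iterative refresh or
  confidence masking is implemented.
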