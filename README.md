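# mdcseg

Two-step semi-supervised segmentation of tubular structures in 3D
grayscale volumes, for the common clinical situation where voxel-level
annotation is scarce: a handful of densely labeled volumes, some volumes
labeled only on scattered axial slices, and many unlabeled volumes.
The motivating application is intestine segmentation in abdominal CT,
where a 3D network alone underfits the few labeled volumes while a 2D
network sees thousands of labeled slices but no through-plane context.

## The method

**Step 1.** A 2D U-shaped slice network with windowed self-attention,
$f^s$, is trained on the axial slices of the labeled volumes with the
compound supervised loss

$$L_{sup} = \alpha\,L_{ce} + (1-\alpha)\,L_{dice}, \qquad \alpha = 0.3,$$

where $L_{dice}$ is soft Dice on the foreground class with smoothing
$s = 10^{-5}$.

**Pseudo-labels.** The frozen $f^s$ predicts every axial slice of every
unlabeled sliding-window patch; slice probability maps are merged back
into the patch and discretised by argmax (ties to background):
$P^*_u = \operatorname{argmax} f^s(D^u_{slice})$. Pseudo-labels are cached
on disk, keyed by (case, patch origin, checkpoint fingerprint), and never
refreshed.

**Step 2.** A 3D convolutional U-Net, $f^c$, is trained on labeled patches
with $L_{sup}$ and on unlabeled patches with a Dice-only consistency loss
against the frozen pseudo-labels,

$$L_{total} = L_{sup}\big(f^c(D^l), G\big) + L_{dice}\big(f^c(D^u), P^*_u\big).$$

Training uses SGD (momentum 0.9) under a poly schedule
$lr = 0.01\,(1-e/E)^{0.9}$, early stopping on validation Dice (patience
30, cap 500 epochs), flip augmentation (plus image-only cut-out in 3D),
and best-validation checkpoint selection. Whole-volume inference crops
overlapping patches, averages their probabilities where they overlap, and
takes the argmax. Metrics (foreground Dice / precision / recall) are
computed **only on labeled slices**, experiments are repeated over three
seeds (per-case mean over seeds, then mean ± SD over cases), and paired
methods are compared with the two-sided Wilcoxon signed-rank test.

Both networks are implemented in the package (forward and backward, with
a compiled convolution core); no deep-learning framework is required, and
every gradient is verified against finite differences in the tests. A
synthetic phantom module generates tubular-foreground cohorts — curved
tubes, touching confounder blobs within ±10% of tube intensity, sparse /
dense / absent annotations — so the whole pipeline is testable without
clinical data.

## Worked example

```r
library(mdcseg)

# a synthetic cohort: 2 densely labeled + 6 unlabeled training volumes,
# 2 validation and 4 test volumes of 64 x 64 x 32 voxels
cohort <- make_cohort(n_labeled = 2, n_unlabeled = 6, n_val = 2, n_test = 4,
                      spec = phantom_spec(), seed = 232)
cohort
#> <cohort> 2 labeled + 6 unlabeled train, 2 validation, 4 test

# two-step pipeline vs supervised-only baseline, three seeds each
# (~10 min on one CPU)
ex <- two_step_experiment(cohort, desk_config(), seeds = 11:13)
ex
#> <mdcseg_experiment> 3 seed(s), 4 test case(s)
#>   two-step  Dice 0.9127 +/- 0.0186
#>   baseline  Dice 0.8749 +/- 0.0356
#>   Wilcoxon signed-rank on paired Dice: p = 0.1250 (n = 4)

glance(ex)       # one-row comparison of the two arms
tidy(ex)         # per-seed, per-case Dice/precision/recall
```

The two-step arm reaches a mean test Dice of 0.91 despite seeing dense
labels for only two volumes; the supervised-only baseline, trained
identically but without the consistency term, trails it on every test
case (with only 4 paired cases the exact Wilcoxon p cannot fall below
0.125). Precision is the discriminating metric here (0.85 vs 0.80 in this
run): both arms recall the tubes almost completely, but the baseline is
fooled more often by the confounder blobs, whose intensity matches the
tubes and which only shape context can reject.

Lower-level entry points mirror the pipeline stages: `train_step1()`,
`pseudo_label_cohort()`, `train_step2()`, `infer_volume()`,
`evaluate_cohort()`, `aggregate_seeds()`, `wilcoxon_signed_rank()`;
`read_volume()` / `write_volume()` and `resample_isotropic()` handle
NIfTI volumes with anisotropic spacing.

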