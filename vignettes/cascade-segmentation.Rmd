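---
title: "Coarse-to-fine cascade segmentation of micro-lesions: models, losses and phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine cascade segmentation of micro-lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cerebral microbleeds (CMBs) appear on susceptibility-weighted MRI (SWI) as
small ovoid hypointense spots, under 10 mm in diameter and usually only a few
millimetres. Segmenting them automatically is hard for two reasons: the
foreground is a vanishing fraction of the slice (a 5-pixel lesion in a
96x128 image is 0.04% of the pixels), and the brain is full of lookalikes —
veins, calcifications and susceptibility artefacts are equally dark and
similarly sized. A single network looking at the whole slice tends to either
miss lesions (when trained on a balanced loss) or drown in false positives
(when trained for sensitivity).

`microseg` implements the standard answer to this dilemma: a two-stage
cascade.

1. **Coarse stage** — a residual U-Net scores the whole slice. It is trained
   with a heavily sensitivity-weighted loss, so its job is to miss nothing;
   false positives are acceptable here.
2. **Fine stage** — for each candidate (a connected component of the
   thresholded coarse map), a fixed-size square ROI centred on the candidate
   is segmented at full resolution by a second network (the FRN). Pixels
   outside every ROI are background by construction, which is the mechanism
   that suppresses far-field false positives.

## Networks

**Residual U-Net (coarse).** Five encoder stages with output channels
32, 64, 128, 256, 512. Stage 1 is a single 3x3 convolution; stage 2 is a
stride-2 transition convolution followed by three identity-shortcut residual
blocks (S1); stages 3 and 4 each open with a projection-shortcut residual
block (S2, stride 2) followed by three S1 blocks; stage 5 runs two S1 blocks
and closes with a stride-2 S2 block. A residual block computes
`ReLU(h(x) + F(x, W))` with `F` = conv-ReLU-conv and `h` = identity (S1) or a
1x1 projection (S2). The decoder uses bilinear interpolation instead of
transposed convolutions (no extra parameters) and fuses each encoder stage
through a skip concatenation and a 3x3 convolution; a 1x1 convolution and a
logistic sigmoid produce the per-pixel probability. Inputs must be divisible
by 16 (four stride-2 steps).

Two compositional details are not pinned down by the five-stage listing
above and were fixed as design choices: stage 4 mirrors stage 3 with 256
channels, and stage 2 (which contains only channel-preserving S1 blocks,
yet must halve resolution and double channels) opens with a plain stride-2
transition convolution. Both follow the 32-64-128-256-512 doubling pattern
the stage listing implies.

**FRN with R-ASPP (fine).** The full-resolution network never downsamples:
conv-in (to 32 channels), three S1 blocks, one residual atrous spatial
pyramid pooling (R-ASPP) block, three more S1 blocks, conv-out, sigmoid —
every feature map lives at the ROI's resolution. R-ASPP runs three parallel
3x3 dilated convolutions plus a global-average-pooling branch, sums them,
fuses with a 1x1 convolution and adds the input back through an identity
shortcut. Two dilation-rate conventions circulate for this
block, (6, 8, 12) and (4, 8, 12); the package defaults to (6, 8, 12) and
exposes the set in `frn_spec()`.

A 16x16 ROI is smaller than the 25-pixel span of a dilation-12 kernel. All
four supported ROI sizes (16, 32, 64, 128) must nevertheless be accepted, so
the receptive-field minimum is defined by the *smallest* dilation
(2 x 6 + 1 = 13 pixels under the defaults); larger branches rely on zero
padding, exactly as in the reference networks this block descends from.

**No normalization layers.** Batch statistics are meaningless at batch size
1-6 on a CPU, so this implementation uses none. Instead the last
convolution of every residual branch is
zero-initialized, so each residual block starts as the identity and the
activation scale stays bounded at initialization — the usual normalization
substitute in unnormalized residual networks. A practical consequence
verified in the test suite: with the residual branch weights zeroed, a chain
of S1 blocks is exactly the identity on nonnegative input, and its Jacobian
is the identity — the gradient reaches layer `l` undamped through the
shortcut path.

## The joint loss

For probabilities `p` and binary labels `y` over `N` pixels:

* binary cross-entropy `L_bce = -(1/N) sum[y log p + (1-y) log(1-p)]`
  (predictions clipped at 1e-7);
* Dice loss `L_dice = 1 - (2 sum(p y) + s) / (sum(p) + sum(y) + s)`;
* sensitivity loss `L_sen = 1 - (sum(p y) + s) / (sum(y) + s)` — the soft
  missed-diagnosis rate;
* total `L = L_bce + L_dice + lambda * L_sen`.

`lambda` is the sensitivity/precision knob: 10 in the coarse stage (find
everything), 1 in the fine stage (balance). The smoothing term `s` defaults
to 1 so empty-foreground images are well defined (`smooth = 0` gives the
exact textbook formulas; the test suite checks both against brute-force
enumeration). Losses are computed per image and averaged over the batch,
matching per-case mean ± SD reporting.

During optimization the cross-entropy term is back-propagated in logit space
(the fused `(p - y)/N` form). This matters: chaining `dL/dp` through the
sigmoid derivative dies when the sigmoid saturates at double-precision 0
or 1, and an early over-confident network becomes untrainable. The fused
form keeps the corrective gradient alive; the Dice and sensitivity terms are
chained through the sigmoid normally. Analytic gradients are verified
against central finite differences (relative error <= 1e-3).

## Training protocol

Adam (beta = 0.9/0.999, no weight decay, constant learning rate), batch
size 6, early stopping on the validation total loss with patience 25, and
five-fold cross-validation with per-fold mean ± SD reporting. The clinical
protocol trains up to 500 epochs at learning rate 2e-4 on 352x448 slices;
those remain the `train_config()` defaults.

The desk-scale experiments in the test suite and `scripts/acceptance.R`
shrink the problem, not the topology: 96x128 phantoms, channel widths
divided by 8-16 (`width_factor`), 6-12 epochs, learning rate 5e-3. The
larger rate is deliberate — a few hundred Adam steps at 2e-4 cannot move
He-initialized weights materially, so the clinical rate belongs with the
clinical epoch budget, and the desk-scale budget gets a correspondingly
larger step.

Two safeguards make short-budget training reproducible across seeds. Each
batch gradient is clipped to a global L2 norm of 5 (`grad_clip`), damping
the sensitivity-dominated updates of the first epochs. And because the
lambda = 10 objective occasionally collapses from a random initialization
into a degenerate optimum — most of the field predicted foreground, or no
true foreground found at all — a finished run is checked on the validation
set and, if degenerate, retrained from a different derived initialization
(`max_restarts`, default 2), exactly as restarted k-means handles its bad
local minima. On a 3-dataset x 3-seed sweep this took desk-scale coarse
training from 5/9 healthy runs to 9/9.

Fine-stage training samples ROI patches rather than slices: positives are
windows centred on ground-truth components with ±4 px jitter; hard negatives
are windows centred on the trained coarse stage's false-positive components
(capped at a 1:1 ratio). This converts the cascade's purpose — "exclude the
coarse stage's false positives" — into a training signal.

## The phantom generator

No clinical data ships with the package; `generate_phantom_dataset()`
produces the study conditions instead. Each slice is a smooth brain-like
textured background (bilinearly upsampled low-resolution Gaussian field,
intensity ~0.55 ± 0.08) on which the generator places:

* **lesions** — anti-aliased filled ellipses, darker than their surroundings
  by a contrast offset drawn from 0.25-0.5 of the intensity scale. Counts
  (1-4 per slice), equivalent diameters (2-6 mm at 0.5 mm/pixel; clinical
  CMBs are < 10 mm and mostly 2-5 mm), and eccentricities (0-0.5) are drawn
  per lesion. The diameter is interpreted as the *equivalent* diameter
  `2*sqrt(ab)` so eccentric lesions keep their area in range, and a lesion
  whose rasterized component falls outside the configured range is redrawn —
  the range is a hard guarantee on the masks. Lesions are placed with
  separation margins so the mask component count always equals the drawn
  lesion count.
* **vein-like mimics** — thin dark random-walk curves (0-3 per slice) that
  darken the image but contribute nothing to the mask. They reproduce the
  visual confuser that makes the detection problem non-trivial.
* **noise** — Gaussian, SD 0.02 after normalization.

What the phantom does *not* emulate: MR susceptibility physics, the blooming
effect, anatomy (ventricles, skull), intensity inhomogeneity fields, or 3D
continuity of veins across slices. Passing the desk-scale acceptance runs
therefore demonstrates that the cascade mechanism, losses, and training loop
work as designed — not clinical-grade performance on real SWI; the clinical
numbers in the literature come from hundreds of epochs on hundreds of
annotated patient slices.

Augmentation follows the stated protocol: intensity shift ~ U(-0.2, 0.2) and
scale ~ U(0.8, 1.2) ("translation and scaling with support (-0.2, 0.2)",
read literally as interval bounds), rotation up to 180 degrees with 30%
probability (bilinear for images, nearest-neighbour for masks),
horizontal/vertical flips each with 30% probability, and additive Gaussian
noise. All geometric transforms act identically on image and mask. Rotation
pads the image with its median intensity and the mask with background: on
images whose lesions are defined by darkness, constant-0 corners masquerade
as giant hypointense structures and demonstrably destabilize coarse-stage
training.

One deliberate protocol deviation at desk scale: the end-to-end and
sensitivity-weight experiments train with augmentation off. Augmentation
exists to stretch scarce clinical data; phantom data is unlimited by
construction, so augmentation buys no generalization here and only adds
optimization noise to very short training budgets. The stack itself is fully
implemented, unit-tested, and on by default in `train_config()`.

## Numerical choices and degenerate inputs

* Min-max normalization of a constant image returns zeros (divide-by-zero
  convention); normalization is idempotent otherwise.
* Binarization uses `>= threshold`; the default threshold is 0.5 at both
  stages (the sources never state one).
* Candidates are 8-connected components; components below
  `min_component_area` (default 1, i.e. keep all) are dropped.
* ROI windows are translated to fit inside the image at borders, never
  zero-padded, keeping the fine network's input statistics uniform. One ROI
  is cut per candidate even if the candidate outgrows the window (possible
  at size 16) — a known limitation.
* Overlapping ROI probabilities fuse by elementwise max (favouring
  sensitivity); `"mean"` is available. Fusion happens before the final
  threshold.
* Metric edge cases: if truth and prediction are both empty all six metrics
  are 1; if exactly one is empty, undefined ratios are 0. The per-image
  false-positive count (`fp_avg`) follows the detection convention: a
  predicted component with zero overlap with any truth component is one
  false positive; a truth component is detected iff some predicted component
  overlaps it by at least one pixel.
* The PR curve treats every distinct predicted value as a threshold
  (`>=` rule) on pooled pixels; AP is the area under the recall-sorted step
  curve.

## Problem sizes used by the test suite

Chosen as the package's own desk-scale study conditions: formula oracles use
1,000 random 8x8 mask/probability pairs; the gradient check uses an 8x8
patch through a width/16 FRN with dilations (1, 2, 3); single-image
memorization trains a width/8 coarse net for 200 epochs at learning rate
5e-3; the end-to-end run trains on 300 phantoms, validates on 60, 12 coarse
+ 6 fine epochs at width/16; the sensitivity-weight comparison trains 3 seed
replicates of each of lambda = 0 and lambda = 10 on a 40/10 split for 6
epochs.

## Known limitations

* CPU-only, one image per forward pass; no 3D context (slices are treated
  independently), no test-time augmentation, no multi-scale ROI ensembling.
* Pretraining of the coarse stage is not modelled: initialization is random
  (He) with zero-initialized residual-branch tails; `load_checkpoint()`
  supports warm starts.
* The phantom's realism is calibrated only by stated lesion geometry (size,
  shape, hypointensity) — background texture and contrast of real SWI are
  not quantified anywhere in the source material.
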