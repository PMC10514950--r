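---
title: "Deep ensemble segmentation of cervical cytology images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep ensemble segmentation of cervical cytology images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Cervical cytology screening rests on per-cell morphology: nuclear size and
shape, and the nucleus-to-cytoplasm ratio.  Both the whole-cell
(cytoplasm) region and the much smaller nuclear region therefore need
per-pixel delineation.  `cytoseg` treats the two as **independent binary
semantic-segmentation tasks**: the positive class is cytoplasm (or
nucleus), the negative class is background.  Decoupling the tasks keeps
the class balance, loss weighting and thresholds of each task independent.

Each task is solved by an **ensemble of encoder-decoder convolutional
networks**.  A base model maps an 8-bit RGB image to a per-pixel
foreground probability map through a sigmoid head.  Four base models are
combined by *unweighted averaging*:

$$\mathrm{pred}(x) \;=\; \mathbb{1}\!\left[\frac{1}{M}\sum_{i=1}^{M} p_i(x) > 0.5\right],\qquad M = 4,$$

with a strict inequality, so a pixel at exactly 0.5 is negative (constant
0.5 maps are reachable from symmetric initializations, and the tie rule
is deliberate and tested).  Validation-loss-weighted averaging
(`weights_from_val_losses()`, inverse-loss normalized) is available but
not the default; averaging happens on probabilities, after the sigmoid,
not on logits.

The four base models are U-Net and U-Net++ decoders over ResNet-34 and
DenseNet-121 encoders.  DeepLabV3 and DeepLabV3+ heads over ResNet-34/50
are also constructible (`list_supported()`), as the candidate pool from
which the four were selected.  Architecture fidelity is pinned by an
exact oracle: the full-width trainable-parameter counts of all eight
combinations (e.g. 24,436,369 for U-Net/ResNet-34) are asserted in the
test suite, which fixes every decoder width, skip wiring and bias choice.

## The computation engine

The networks run on a compact CPU engine (Rcpp/RcppArmadillo) rather than
a GPU framework: convolution is im2col plus one BLAS multiplication per
layer over the whole mini-batch, with batch normalization, max/average
pooling, nearest and bilinear upsampling, dense concatenation, residual
addition, depthwise (separable) convolution for the DeepLabV3+ head, and
a fused sigmoid + class-weighted binary cross-entropy on the logits.
Reverse-mode gradients are implemented for every operation and are
checked against central finite differences in the test suite.  Everything
is double precision; the `amp` flag of `train_config()` is accepted for
interface compatibility and ignored (mixed precision is a GPU-throughput
device with no benefit here, and it is excluded from determinism
contracts anyway).

Full-width models are buildable and countable without materializing
weights; training at full width on a CPU is possible but slow, so the
package's own experiments use `tiny = TRUE` quarter-width variants.

## Training recipe

`train_config()` defaults encode the full-scale recipe:

* batch size 32, 20 epochs, Adam (beta1 0.9, beta2 0.999) wrapped in
  lookahead with `k = 5`, `alpha = 0.5`;
* initial learning rate 1e-3, multiplied by 0.1 at 30%, 60% and 90% of
  the epoch budget (`floor(fraction * epochs)`, 0-based epochs);
* label smoothing `eps = 0.1`: binary targets become
  `y(1 - eps) + eps/2`, i.e. {0.05, 0.95}.  The smoothing form for binary
  targets is the symmetric reading; the positive-class weight multiplies
  the target-side term, which keeps `pos_weight = 1` exactly equal to
  plain binary cross-entropy;
* positive-class weight 1 for cytoplasm, 8 for nucleus.  Nuclei occupy a
  few percent of the pixels (see the generator below), hence the
  up-weighting for that task only;
* real-time augmentation with four transform families, each applied with
  probability 0.5: horizontal/vertical flips (image and masks together),
  brightness/contrast, gaussian blur, hue/saturation (image only).
  Magnitudes are exposed via `default_aug_params()`;
* every model is trained `n_runs = 3` times and the run with the lowest
  validation loss wins (`select_best()`, ties to the earliest run).
  Validation loss uses the same smoothed, weighted loss as training.

Two additions are the package's own engineering choices:

* **Head-bias prior initialization** (`head_bias_prior = TRUE`): the
  segmentation-head bias starts at the class-prior logit of the training
  set.  For rare-positive tasks this removes the early phase in which the
  optimizer only drives down bulk false positives; it is the standard
  initialization trick for imbalanced dense prediction and changes
  nothing about the loss or the data.
* **`tiny_train_config()`** fixes the desk-scale conditions: batch size
  4, 3 epochs, one run, and *no* learning-rate decay.  With a 3-epoch
  budget the 30/60/90% milestones collapse to `floor(0.9) = 0`, i.e.
  decay at epoch 0; holding the base rate is the sensible reading of the
  schedule for short runs.  The smaller batch size gives the optimizer
  ~45 steps per epoch at n = 180, which a 3-epoch run needs; the
  full-scale default stays 32.

`init = "imagenet"` constructs the same graphs and records the ImageNet
input normalization (channel means 0.485/0.456/0.406, SDs
0.229/0.224/0.225), but pretrained encoder weights cannot be bundled with
a source-only package: materialization requires a locally supplied
weights file (`options(cytoseg.imagenet_weights = ...)`).  The package's
own runnable experiments therefore use `init = "scratch"` ([0,1] input
scaling, He-normal weights); transfer learning remains available to users
who convert torchvision weights once.

## Synthetic data: what it emulates and what it does not

`synthetic_config()` / `generate_sample()` produce Pap-stain-like images
with exact ground truth, deterministic per `(seed, index)` so datasets
are order-independent.  Emulated features of real cytology crops:

* a handful of overlapping elliptical cells (default 3-8 per frame,
  semi-axes 12-21% of the frame side), drawn back-to-front with the
  semantic (union) mask convention;
* exactly one darker nucleus per cell, geometrically contained in its
  cell: the nucleus shares the cell's orientation, its semi-axes are a
  fraction (default 0.18-0.32) of the cell's, and its centre offset is
  bounded by `1 - fraction` in normalized coordinates, which guarantees
  the nucleus-within-cytoplasm invariant analytically, before
  rasterization;
* cells cropped by the frame border (default probability 0.3 per cell),
  as happens in real crop-based datasets;
* near-white, slightly blue background; per-cell cyan-to-pink washes and
  dark purple nuclei, so hue/saturation augmentation acts on meaningful
  color structure; gaussian blur and pixel noise.

Under the defaults the nucleus-positive fraction is ~2-3% of pixels
(tested to be < 5% on average), which is exactly the imbalance that
motivates the nucleus `pos_weight` of 8, while cytoplasm occupies roughly
a third of the frame.

Not emulated: chromatin texture, dyskaryotic morphology, staining
artifacts, out-of-focus debris, instance ground truth.  Passing the
synthetic study shows the pipeline *learns and composes correctly*; it
does not certify clinical-grade accuracy on real slides.

## Evaluation methodology

All metrics are **micro-averaged**: confusion counts are accumulated over
every pixel of every image and the metric is computed once.  This matches
the pixel-level bootstrap and makes results invariant to how the pixel
population is grouped into images (a tested property).  Dice uses the
standard 2TP/(2TP+FP+FN); published versions of this table family
occasionally misprint the denominator, and the standard form is the only
one consistent with the reported values.  Vacuous denominators return 1
(no error was possible).  Report tables round to four decimals, halves
away from zero.

Confidence intervals are **pixel-level percentile bootstrap** with B =
500 replicates at 95%: resampling N pixels with replacement is
distributionally identical to one multinomial draw over the four
confusion categories, which is what the implementation does (O(1) per
replicate); the equivalence is enforced by a naive-resampling oracle
test.  BCa corrections are not used - with millions of pixels the
percentile interval is already essentially symmetric and the published
convention names only the plain bootstrap.

Predictor comparisons use a **paired pixel bootstrap**: for each
replicate, every image's pixels are resampled once and both predictors
are scored on the same resample.  The sufficient statistic is the
per-image joint 8-category table over (pred_A, pred_B, truth)
(`joint_confusion()`); marginal counts alone cannot express the pairing,
which is why `paired_bootstrap_test()` takes masks or joint counts.  The
two-sided p-value is `2 min(frac(diff <= 0), frac(diff >= 0))`, floored
at 1/B.  No multiple-testing correction is applied across metrics or
tasks.  ROC curves pool pixels (seeded subsampling above
`max_roc_pixels`) and the AUC is the tie-aware ranking probability, which
equals trapezoidal integration of the curve (tested to 1e-9).

## The desk-scale study

The package's own end-to-end experiment (run by the acceptance script and
asserted in the tests) uses: 200 synthetic 64x64 training samples split
0.9/0.1 at the sample level, 30 fresh test samples from a disjoint seeded
stream, the four tiny base models per task, `tiny_train_config()` (3
epochs, batch 4, one run), unweighted averaging at threshold 0.5, and
B = 500 bootstrap.  Problem sizes were chosen as the smallest study that
still exercises every pipeline stage with four distinct architectures.
On these conditions the cytoplasm ensemble reaches Dice >= 0.80 and the
nucleus ensemble >= 0.60, and each task's ensemble Dice is at least the
arithmetic mean of its members' - the qualitative signature of
probability averaging that also holds in the full-scale published
setting.

## Data formats and conversion

The disk format is lossless: `<id>.png` (8-bit RGB), `<id>_cyto.png`,
`<id>_nuc.png` (single-channel, {0,255}).  Masks are *binarized at
read time with a strict >127 threshold* (`binarize_stored_mask()`), so
datasets that went through lossy JPEG at some point in their history read
identically to clean PNGs.  MATLAB v7.3 (.mat/HDF5) containers are
converted by `convert_cx22_container()`; the HDF5 decode runs in the
system Python (h5py/Pillow) because no R HDF5 reader is available in the
package's dependency footprint, and dataset keys are auto-discovered by
shape - the stack with a channel axis of 3 is the image; of the two mask
stacks the one with larger foreground is cytoplasm (nuclei are the
minority class) - with a manual `keys` override for containers whose
layout defeats the heuristic.  The predefined test split of a converted
dataset is never re-split.

## Known limitations

* Pixel-level semantics only: no instance identification or per-cell
  measurements; touching cells merge in the mask.
* The engine is CPU-bound; full-width training at 512x512 scale is out of
  practical reach, which is why full-width fidelity is asserted through
  parameter counts and forward contracts rather than training runs.
* Transformer architectures are out of scope: vision transformers need
  substantially more training data than CNN encoder-decoders and tend to
  collapse at cytology-dataset scale, so the zoo is CNN-only.
* The synthetic generator's color statistics are plausible but
  unconstrained by measured staining distributions.
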