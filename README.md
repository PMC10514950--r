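# cytoseg

Deep ensemble segmentation of cervical cytology (Pap smear) images in R.

Automated cytology screening needs per-pixel delineation of whole-cell
regions (cytoplasm) and of the much smaller, darker nuclei — the
morphology that drives diagnosis (nuclear size/shape, nucleus-to-cytoplasm
ratio).  `cytoseg` implements this as two independent binary
semantic-segmentation tasks, each solved by an ensemble of encoder–decoder
convolutional networks.  The package is aimed at researchers who want a
fully scripted, seeded, CPU-reproducible version of the ensemble pipeline:
data conversion, synthetic ground truth, training, averaging, and
bootstrap evaluation.

## The method

Each base model maps an RGB image to a per-pixel foreground probability
p(x).  The ensemble prediction for every pixel is the unweighted average
of M = 4 base models, thresholded strictly at 0.5:

    pred(x) = 1[ (1/M) Σᵢ pᵢ(x) > 0.5 ]

The four base models are U-Net and U-Net++ decoders over ResNet-34 and
DenseNet-121 encoders; DeepLabV3 and DeepLabV3+ heads (ResNet-34/50) are
also constructible as the candidate pool.  Architecture fidelity is pinned
by an exact oracle: the full-width trainable-parameter counts of all eight
combinations (24,436,369 for U-Net/ResNet-34, 13,607,633 for
U-Net/DenseNet-121, 26,078,609 and 30,072,273 for their U-Net++
counterparts, …) are asserted in the test suite.

Training follows a fixed recipe: real-time augmentation (flips,
brightness/contrast, blur, hue/saturation), label-smoothed (ε = 0.1)
binary cross-entropy with positive-class weight 8 for the rare nucleus
class, Adam wrapped in lookahead (k = 5, α = 0.5), learning rate 1e-3
decayed ×0.1 at 30/60/90% of the epochs, and repeat-3 selection by
validation loss.  Evaluation is micro-averaged Dice / sensitivity /
specificity (Dice = 2TP/(2TP+FP+FN)) with pixel-level percentile
bootstrap CIs (B = 500) and paired bootstrap comparisons.

The networks run on a compact built-in CPU engine (Rcpp/RcppArmadillo:
im2col convolutions, batch norm, pooling, upsampling, fused weighted-BCE
loss) with finite-difference-checked gradients — no external deep-learning
framework is required.

## Worked example

A complete miniature study — synthetic Pap-stain-like data, four
quarter-width ("tiny") base models per task, 3 epochs each, ensemble,
bootstrap evaluation — runs in a few minutes on one CPU:

```r
library(cytoseg)

pc <- pipeline_config(
  data = list(synthetic = synthetic_config(image_size = c(64, 64), seed = 7),
              n_train = 200, n_test = 30),
  specs = base_model_specs(tiny = TRUE),
  train_cyto = tiny_train_config("cytoplasm", seed = 1),
  train_nuc  = tiny_train_config("nucleus", seed = 1),
  eval = eval_config(B = 500, seed = 1),
  out_dir = "run1", seed = 1)
mf <- run_pipeline(pc)

mf$tasks$cytoplasm$ensemble_dice    # [1] 0.9529732
mf$tasks$cytoplasm$member_mean_dice # [1] 0.9320807
mf$tasks$nucleus$ensemble_dice      # [1] 0.7777285
mf$tasks$nucleus$member_mean_dice   # [1] 0.7188438
```

The ensemble Dice exceeds the arithmetic mean of its four members on both
tasks — the qualitative signature of probability averaging.  `run1/`
contains checkpoints, per-epoch history CSVs, JSON/CSV reports with
bootstrap CIs and the ensemble-vs-best-model paired p-value, overlay
PNGs (predicted cytoplasm and nucleus contours drawn on the test images),
and a manifest listing every artifact.

Real Cx22-style data enters through the converter:

```r
convert_cx22_container("Cx22_train.mat", "data/train")
samples <- load_dataset("data/train")
split <- split_train_val(sapply(samples, `[[`, "id"), ratio = 0.9, seed = 1)
```

A thin command-line front end with the same subcommands
(`synth`, `convert-cx22`, `train`, `predict`, `ensemble-predict`,
`evaluate`, `compare`, `run`) is installed at
`system.file("cli", "cytoseg", package = "cytoseg")`.

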