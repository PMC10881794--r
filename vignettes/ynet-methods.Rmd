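---
title: "Joint segmentation and classification of lymph-node ultrasound: model and methods"
author: "ynetus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint segmentation and classification of lymph-node ultrasound: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Metastatic cervical lymph nodes of thyroid cancer are screened with B-mode
ultrasound before fine-needle aspiration. Reading these images is strongly
operator-dependent: a node must first be found among vessels, muscle and
trachea, and then judged benign or malignant from morphological cues —
elongated nodes with a bright fatty hilum are usually benign, while rounded
nodes that have lost the hilum and carry punctate echogenic foci
(microcalcifications) are suspicious. `ynetus` implements a Y-Net: a
U-Net-style encoder/decoder that *segments* the target node and, from the
same shared encoder, *classifies* the image as benign or malignant — the
two outputs a sonographer needs simultaneously.

## The network

The model (`build_ynet()`, configured by `ynet_config()`) is built from
three ingredients that the field's segmentation networks contributed:

* **Residual encoder with ESP blocks.** Each of the `encoder_levels`
  stages (default 4) downsamples by a stride-2 convolution and then applies
  a residual unit whose inner 3×3 convolution is replaced by an
  *efficient spatial pyramid*: parallel 3×3 convolutions at dilations
  `esp_dilations` (default 1/2/4/8) whose outputs are fused hierarchically
  (each branch adds the previous partial sum), concatenated and projected
  back by a 1×1 convolution. This gives a large receptive field at a small
  parameter cost.
* **Pyramid pooling bottleneck.** At the bottleneck (16×16 for a 256×256
  input), feature maps are adaptively average-pooled to bins of
  `ppm_bins` (default 3/5/7/9), reduced 1×1 by the number of bins,
  bilinearly upsampled and concatenated with the input map, then fused
  1×1 — the PSPNet recipe for injecting global context, which matters
  because a neck frame is a crowded scene.
* **Two heads, dual skips.** The decoder mirrors the encoder with the same
  ESP blocks. At each resolution it receives (a) the standard U-Net
  concatenation skip from the last encoding block and (b) the Y-Net
  *superposition* skip — an element-wise addition of the first encoding
  block at that resolution. The segmentation head produces a
  single-channel lesion-vs-background logit map; the classification branch
  applies global average pooling to the post-pyramid bottleneck features
  followed by a small two-layer perceptron producing the C = 2 class
  logits. Setting `classification_only = TRUE` removes the decoder and
  segmentation head entirely (the ablation variant).

Channel widths (16 at the first stage, doubling per stage), the encoder
depth, activation functions (batch-norm + ReLU in every block) and the way
the classification branch taps the trunk are not pinned down by the
original Y-Net description; they are deliberate design choices here, all
exposed in `ynet_config()`. Two are worth flagging:

* the segmentation logits are computed at half resolution (128×128) and
  bilinearly upsampled to the input size. Lesion boundaries in this task
  are smooth ellipse-scale contours, so the half-resolution head changes
  the Dice of a well-fit mask by well under a pixel's worth while roughly
  halving the computational cost of training;
* the classification branch uses one hidden layer (half the bottleneck
  width) rather than a bare linear readout: shape-level cues such as the
  axis ratio are not linear functions of pooled features.

All layers are implemented in this package (im2col + BLAS convolutions,
fused batch-norm/ReLU kernels, bilinear and adaptive-pooling resamplers in
C++), with exact reverse-mode gradients via a small R tape. The test suite
verifies every layer's gradient against central finite differences.

## Loss and training protocol

Both heads are trained with cross-entropy (`joint_loss()`):

$$L = L_\text{seg} + \lambda\, L_\text{cls},$$

where $L_\text{seg}$ is the mean per-pixel binary cross-entropy of the
logit map against the binary mask and $L_\text{cls}$ the cross-entropy of
the class logits against the image-level label. The weighting $\lambda$
defaults to 1 — the protocol states only that the total loss combines the
two terms — and is exposed in `train_config()`.

Training (`ynet_fit()`, `ynet_train()`) uses mini-batches of 8 images and
Adam at an initial learning rate of 0.001 (the protocol names only the
initial rate; Adam is this package's choice, exposed in the
configuration). No learning-rate schedule or early stopping is used.
Augmentation applies a seeded isotropic scale jitter in [0.9, 1.1] (image
and mask identically) and a gamma jitter in [0.8, 1.25] (image only) —
scaling and intensity enhancement only, since no flips or rotations are
part of the protocol.

Data are split by *patient*, never by image (`split_dataset()`): about one
fifth of patients form the held-out test set, and the remaining patients
are partitioned into 5 cross-validation folds whose sizes differ by at
most one patient. `ynet_train()` records per-fold validation Dice and
accuracy, then retrains on the full training partition to produce the
final model (the protocol is silent on fold aggregation; retraining on
everything is this package's choice). One master seed fans out to the
split, initialisation, augmentation and batch order, so runs are
bit-reproducible.

The classification operating point is not fixed at 0.5: following the
protocol, the cutoff is chosen on an ROC curve (`choose_cutoff()`
maximises Youden's J, breaking ties toward higher specificity), computed
here on the training set.

## Evaluation suite

* **Dice** (`dice()`): $2|A\cap B|/(|A|+|B|)$. Two empty masks score 1
  (agreement that no lesion is present) and the value is flagged; this
  case cannot arise in training data, where masks are non-empty by
  construction.
* **Diagnostic metrics** (`diagnostic_metrics()`): Sen = TP/(TP+FN),
  Spe = TN/(TN+FP), Acc, PPV, NPV, +LR = Sen/(1−Spe), −LR = (1−Sen)/Spe,
  with malignant as the positive class. A zero denominator marks the
  metric *undefined* rather than silently zero; a likelihood ratio with a
  positive numerator over zero is `Inf` by the usual convention.
* **ROC/AUC** (`roc_auc()`): operating points at every distinct score
  (ties grouped), AUC by the trapezoidal rule, which then equals the
  Mann–Whitney concordance probability — the test suite checks this
  identity exhaustively at small n.
* **Distribution summaries** (`summarize_dice()`): median and quartiles by
  the linear-interpolation (type 7) convention, plus the five-number
  summary for box plots. The quartile convention is unstated in the
  source material; type 7 is R's default and is declared here once.

## The report-dictionary classifier

Free-text ultrasound conclusions are scored against a fixed keyword
dictionary (`diagnosis_dictionary()`): *lymphadenopathy, abnormal lymph
node, metastasis, CA/Ca, suspicious calcification, suspicious necrosis*
read as malignant; *normal lymph node, reactive hyperplasia, normal
structure* as benign. Matching is case-insensitive substring matching on
the normalised text, with two deliberate rules:

* the carcinoma abbreviation (≤ 2 letters) matches whole words only, so it
  cannot fire inside "calcification";
* when both columns match — "abnormal lymph node" literally contains
  "normal lymph node" — the malignant reading wins, because suspicion of
  malignancy is what triggers aspiration.

Reports matching no keyword are *unresolved*: excluded from the confusion
counts but tallied (`evaluate_reports()`). The dictionary is
user-extensible via YAML; the defaults are pinned by tests. The original
clinical reports were presumably not English; the bundled dictionary is
the published English key set, and localisation is left to the user.

## The synthetic phantom generator

No image from the original study is public, so `generate_phantom()` /
`generate_dataset()` provide a seeded stand-in that emulates the features
the method must exploit:

* a smooth tissue background (low-resolution uniform field, bilinearly
  upsampled) multiplied by gamma-distributed speckle with mean 1 (shape 4
  by default) — the simplest multiplicative model that looks like B-mode
  texture;
* one hypoechoic rotated-ellipse lesion at ~40% of background intensity,
  fully inside the frame with a 4-pixel margin; the mask is the exact
  ellipse raster;
* class-dependent morphology mirroring the sonographic signs: benign
  nodes elongated (long/short axis ratio sampled in [2.15, 3.5]) with an
  echogenic hilum stripe present with probability 0.9; malignant nodes
  rounded (ratio in [1.05, 1.45]) with 2–6 bright punctate foci and no
  hilum. The aspect-ratio gap between the classes is intentional, so the
  class signal is redundant (shape + hilum + foci) and learnable by a
  small CPU-trained model;
* distractors and artefacts: a dark vessel (disc or elongated tube) in
  half the frames — the structure the published failure cases confused
  with nodes — and 1–2 bright corner annotation blocks with recorded
  coordinates, standing in for burned-in machine overlays;
* paired report texts drawn from the dictionary keywords of the record's
  class, with a configurable planted error rate.

What the generator does **not** emulate: acoustic physics (attenuation,
shadowing, refraction), real anatomical context, multiple lesions per
frame, Doppler channels, or inter-observer mask variability. Passing the
end-to-end tests therefore shows that the pipeline can learn and measure
the intended morphology signal under realistic noise — not that the model
would reach any particular performance on clinical data.

## Desk-scale experiment and problem sizes

`ynet_synthetic_benchmark()` is the package's end-to-end experiment, also
recomputed by `scripts/acceptance.R`: 250 phantoms (balanced classes),
patient-grouped 80/20 split (~200 training records), 20 epochs for the
joint model and 8 for the classification-only variant, cutoff chosen on
the training ROC, held-out Dice/accuracy/AUC reported. These sizes are the
package's declared desk-scale study conditions: large enough that the
held-out metrics are stable and the class signal is clearly recovered,
small enough to run routinely on a single CPU. The cross-validation path
(`ynet_train()`) is exercised at miniature scale in the tests for the same
reason.

## Numerical choices and degenerate inputs

* Bilinear resampling uses half-pixel centres with edge clamping; masks
  are resampled nearest-neighbour so they stay binary.
* Intensity normalisation is per-image min–max (a constant image maps to
  zeros): scanner-agnostic, with no dataset-level statistics to store —
  the choice matches multi-vendor acquisition, where absolute echo levels
  are not comparable across machines.
* Batch-norm uses batch statistics during training and running statistics
  at inference, so per-image predictions are independent of batch
  composition (asserted by a test).
* Convolutions carry no bias where batch-norm follows (the mean
  subtraction would cancel it).
* Cross-entropies are computed in the numerically stable
  log-sum-exp/softplus forms; perfect predictions give losses that
  underflow to 0 rather than NaN.
* He-normal initialisation throughout, with one exception: the
  segmentation output bias starts at −3, near the logit of the foreground
  prior (a few percent of pixels are lesion). Starting that logit at 0
  makes the first optimisation steps fight the class imbalance with
  violent gradients that can permanently silence the narrow head
  (predicting empty masks forever after); starting at the prior removes
  the hazard.
* All randomness flows from explicit integer seeds through R's RNG, and
  library code restores the caller's RNG state.
* Ties: equal ROC scores are grouped into one operating point; equal
  Youden J breaks toward higher specificity, then toward the higher
  threshold.

## Known limitations

* The original network's exact layer widths are unpublished; this
  implementation is a faithful small-scale rendition of the described
  architecture, not a weight-level reproduction, and no pretrained
  weights exist.
* Training is CPU-only and double-precision; at the default 256×256
  configuration it is sized for hundreds, not thousands, of images.
* The report classifier does no negation handling or synonym expansion
  beyond the fixed dictionary.
* Overlay boxes are taken as metadata (from the generator, or supplied by
  the user for real exports); no automatic overlay detection or OCR is
  attempted.
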