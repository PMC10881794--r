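# ynetus — joint segmentation and classification of lymph-node ultrasound

`ynetus` implements a **Y-Net** for grayscale B-mode ultrasound images of
cervical lymph nodes: a U-Net-style encoder/decoder that outlines the
target node and, from the same shared encoder, a parallel branch that
classifies it as benign or malignant. It is aimed at researchers studying
computer-aided diagnosis of nodal metastasis (e.g. of thyroid cancer), who
need segmentation, classification, a complete diagnostic-metrics suite and
a reproducible synthetic test bed in one place.

The network combines:

* a **residual encoder with ESP blocks** — each stage's inner 3×3
  convolution is replaced by parallel dilated 3×3 convolutions
  (dilations 1/2/4/8) with hierarchical additive fusion;
* a **pyramid pooling bottleneck** (bins 3×3, 5×5, 7×7, 9×9, PSPNet
  style) for global scene context;
* a mirrored **decoder with dual skip connections**: the usual
  concatenation skip plus a Y-Net *superposition* (element-wise addition)
  skip from the first encoding block at the same resolution;
* **two parallel heads**: per-pixel lesion logits (saved as a binary mask
  after thresholding) and a C-dimensional class vector. A
  classification-only variant drops the decoder entirely.

Both heads train jointly with cross-entropy,

```
L = L_seg + λ · L_cls ,
```

under the study protocol: patient-grouped train/test split, 5-fold
cross-validation, batch size 8, initial learning rate 0.001, and a
classification cutoff chosen on the ROC curve (Youden's J). The
evaluation suite covers the Dice similarity coefficient
`DSC = 2|A∩B|/(|A|+|B|)` with median/quartile summaries, and
Sen/Spe/Acc/PPV/NPV with likelihood ratios `+LR = Sen/(1−Spe)`,
`−LR = (1−Sen)/Spe`, plus ROC/AUC. A keyword dictionary classifier scores
free-text ultrasound report conclusions against the same metrics.

Because no clinical image from the motivating study is public, the package
ships a seeded **speckle-phantom generator**: hypoechoic elliptical
"nodes" with class-dependent morphology (elongated benign nodes with an
echogenic hilum; rounded malignant nodes with punctate foci), vessel
distractors, corner machine-overlay artefacts, and paired report texts.
All network layers (convolutions, batch-norm, pooling, resampling) are
implemented in the package itself over `RcppArmadillo`, with exact
reverse-mode gradients verified against finite differences.

## Worked example

```r
library(ynetus)

# a seeded synthetic dataset: phantoms, masks, labels and report texts
ds <- generate_dataset(6, malignant_fraction = 0.5, seed = 7)
r  <- ds$records[[1]]
c(label = r$label, mask_px = sum(r$mask))
#>   label mask_px
#>       1     684
ds$reports[1:3, c("report_text", "label")]
#>                                                         report_text label
#> 1 Conclusion: suspicious calcification, level II-right of the neck.     1
#> 2                       Conclusion: CA, level VI-right of the neck.     1
#> 3           Conclusion: normal structure, level I-left of the neck.     0
```

Record 1 is a malignant phantom: a rounded hypoechoic node of 684 pixels
with punctate foci, its exact ellipse raster as ground-truth mask, and a
report drawn from the malignant keyword column. The metrics suite works on
plain vectors:

```r
diagnostic_metrics(confusion_counts(predicted = c(1,1,0,0,1,0,0,0,1,1),
                                    truth     = c(1,1,0,0,1,1,0,0,0,1)))
#> Sen 80.00%  Spe 80.00%  Acc 80.00%  PPV 80.00%  NPV 80.00%  +LR 4.00  -LR 0.25
summarize_dice(c(0.93, 0.88, 0.97, 0.12, 0.85))
#> Dice over 5 cases: median 0.880 (IQR 0.850-0.930, range 0.120-0.970)
evaluate_reports(data.frame(
  report_text = c("lymphadenopathy, suspicious calcification",
                  "reactive hyperplasia of lymph node"),
  label = c(1, 0)))$metrics
#> Sen 100.00%  Spe 100.00%  Acc 100.00%  PPV 100.00%  NPV 100.00%  +LR Inf  -LR 0.00
```

The sensitivity of 80% reads: of the 5 truly malignant nodes, 4 were
called malignant; the +LR of 4 means a positive call raises the odds of
malignancy fourfold. The end-to-end experiment — generate 250 phantoms,
train the default Y-Net on the ~200 training-patient records for 20
epochs, pick the cutoff on the training ROC, score the held-out patients —
is one call (about 16 minutes on one CPU):

```r
bench <- ynet_synthetic_benchmark(seed = 42)
#> generating 250 phantoms (seed 42)
#> training joint model on 202 records for 20 epochs
#> joint: Dice median 0.937, accuracy 0.896, AUC 0.988
#> training classification-only variant for 8 epochs
#> cls-only: accuracy 0.854, AUC 0.925
```

A held-out median Dice of 0.937 means the predicted mask of a typical
test node overlaps its ground truth almost completely; accuracy and AUC
show both model variants separating the phantom classes far above chance.

A command-line front end mirrors the R API:

```sh
Rscript exec/ynetus simulate --n 200 --malignant-fraction 0.5 --seed 42 --out data/
Rscript exec/ynetus train    --manifest data/manifest.csv --out run/
Rscript exec/ynetus evaluate --pred preds.csv --truth data/manifest.csv --out metrics.json
```

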