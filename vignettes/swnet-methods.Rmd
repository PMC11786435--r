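---
title: "SWNet: model, design choices and desk-scale validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SWNet: model, design choices and desk-scale validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(swnet)
```

## The model

SWNet is a wide, four-stage, multi-branch convolutional network for binary
(benign vs. malignant) classification of dermoscopy images. Its design
principle is width rather than depth: at each stage, four parallel branches
extract features from the same input and are merged by depth concatenation,
so the representation grows as 128, 256, 512 and 1024 channels while the
spatial resolution halves per stage (224 → 112 → 56 → 28 → 14 for the
standard 224 × 224 × 3 input).

Concretely:

* a stem convolution maps 3 → 32 channels at full resolution;
* stage *s* (widths *w* = 32, 64, 128, 256) holds four branches, each a
  stride-1 3 × 3 convolution to *w* channels followed by a stride-2 3 × 3
  convolution at *w* channels; all four branches read the stage input (the
  stem output for stage 1, the previous stage's normalized concatenation
  thereafter);
* the branch outputs are concatenated (4*w* channels) and batch normalized
  ("BNConcat");
* the head is global average pooling (1 × 1 × 1024), fully connected layers
  of 300 and 64 units with dropout *p* = 0.5 between them, a final
  two-unit fully connected layer and a softmax.

Every convolution uses a 3 × 3 kernel, same padding 1, a bias term, and is
followed by batch normalization and a ReLU. The graph therefore contains 33
convolutions (1 + 4 × 4 × 2), 37 batch normalizations (33 + 4), 33 ReLUs, 4
concatenations, 1 pooling, 3 fully connected and 2 dropout nodes — 113
computational layers in total, with 9,368,192 convolutional parameters
(9 · C~in~ · C~out~ + C~out~ summed over the 33 convolutions).

```{r}
g <- build_swnet()
architecture_audit(g)
```

### Resolved ambiguities in the published architecture table

The published layer table under-determines the graph in a few places; the
builder resolves them by internal consistency, and the parameter total
confirms each choice:

* **Branch wiring.** The table lists four convolution pairs per stage but
  not their inputs. All four branches consuming the stage input, each
  ordered stride-1 then stride-2, is the only wiring consistent with the
  listed activation resolutions, and it reproduces the 9,368,192 total
  exactly (weights 9,364,320 + biases 3,872).
* **Channel typos.** Three table cells contradict the channel-sum rule for
  concatenation and the fully connected sizes (the stage-2 concatenation
  must carry 4 × 64 = 256 channels, not 64; the stage-3 first convolution
  reads 256 channels; the second dropout carries 64 features, not 300).
  The builder follows the rule, not the cells.
* **Merge operator.** An "addition layer" is mentioned once in prose, but
  addition cannot turn four 32-channel inputs into 128 channels;
  concatenation (as in the table and figure) is implemented.
* **Convolution biases.** Biases are redundant before batch normalization,
  but the printed parameter total is only reproduced with them; they are
  kept (and the parameter audit counts them).
* **Layer counting.** 113 is obtained by counting convolution, batch-norm,
  ReLU, concatenation, pooling, fully-connected and dropout nodes; the
  input and the terminal softmax are not counted. No other convention sums
  the table's components to 113.

## Training

Training is plain mini-batch SGD on the cross-entropy of the softmax
output, with defaults matching the reference setup: learning rate 0.001,
100 epochs. The reference setup names SGD only; momentum 0.9 and batch
size 32 are package defaults, both configurable. Optional augmentation
(random rotation ±30°, isotropic scaling 0.8–1.2) implements the
rotation/scaling recipe discussed for bias mitigation; it is off by
default. Weights use He (fan-in) initialization; batch-norm layers start at
scale 1 / shift 0 with ε = 10⁻⁵ and running-statistics momentum 0.1. All
randomness (initialization, shuffling, dropout, augmentation) derives from
one seed, so runs are bit-reproducible on a given BLAS.

After the final epoch the batch-norm running statistics are re-estimated
over the training set (aggregated mini-batch statistics). With only ~100
SGD steps at desk scale, the momentum-lagged running averages otherwise
describe an earlier network than the one being evaluated; recalibration
removes that mismatch without touching learned parameters.

Metrics are the standard confusion-matrix rates with malignant as the
positive class: precision TP/(TP+FP), recall TP/(TP+FN), specificity
TN/(TN+FP), accuracy, and F1. F1 is implemented as the harmonic mean
2PR/(P+R): the printed formula omits the factor 2, but the reported
precision 100, recall 99.90 and F1 99.95 satisfy the standard harmonic
mean, so the omission is treated as a typesetting slip. Zero-denominator
rates return 0 with a warning.

## Grad-CAM and the saliency-mass bias statistic

`grad_cam()` follows the standard convention: gradients of the pre-softmax
class score with respect to a chosen feature map are averaged over space to
give one weight per channel; the rectified weighted sum of feature maps is
bilinearly upsampled to the input size and max-normalized. Batch
normalization runs in inference mode and dropout is disabled. The default
target class is the predicted one; the default layer is the last stage's
normalized concatenation. For multi-layer panels, `gradcam_layers()` names
nine representative layers (stem, the last convolution of each stage, and
the four concatenation outputs); the reference figures do not specify
which nine layers they show, so this set is a package choice and
user-overridable.

`saliency_mass(heatmap, mask)` reduces a heatmap to the fraction of its
mass inside a region. With `vignette_mask()` (the annulus outside the clear
central disc) it quantifies how much attention a model pays to the dark
microscope-vignette artifact — the package's operational measure of
shortcut learning.

## Feature fusion

Two fusion modes are provided, matching the two readings of the reference
description: **feature-level concatenation** — per-image deep features
(default: the 1 × 1 × 1024 global-average-pool activation) from several
models/datasets are concatenated with exact provenance and classified by a
ridge-regularized softmax head on standardized features — and **dataset
pooling** — manifests are merged with source tags and the network is
trained end-to-end on the union. CCA- and SVM-based fusion variants are
mentioned as alternatives in the reference but not committed to; they are
out of scope here. The softmax head uses a small ridge penalty (λ = 10⁻³)
because fused features are often perfectly separable at desk scale, where
an unregularized logistic fit diverges.

## The synthetic dermoscopy generator

Real dermoscopy archives cannot ship with a package, so every behavioral
test runs on generated images whose ground truth is known by construction.
The generator emulates the properties the method depends on:

* **Class signal in morphology.** Lesions are radial blobs whose boundary
  is perturbed sinusoidally; malignant lesions are larger, darker, more
  irregular (amplitude 0.15–0.35 vs 0.02–0.08) and carry 2–4 dark
  variegation patches (benign: 0–1). The irregularity ranges are disjoint,
  so a threshold on the generative parameters classifies perfectly — the
  labels are information-bearing by construction.
* **Skin tone** is a base-canvas color drawn from six Fitzpatrick-inspired
  anchors, recorded as a covariate only.
* **Confounds.** A multiplicative cosine-falloff vignette darkens the
  periphery outside a clear central disc (fraction 0.7 of the half-side by
  default), and dark 1–3 px Bezier strokes emulate hair. Both are applied
  per class with configurable probabilities, so the label–artifact
  association (phi coefficient) can be dialed from 0 to ±1.

What the generator does **not** emulate: dermoscopic texture (pigment
networks, streaks), camera noise, color calibration differences, lesion
segmentation difficulty. Passing tests therefore demonstrate that the
architecture, optimizer, saliency and fusion machinery behave as specified
on images whose decision-relevant structure is known — not that the
network reaches any particular accuracy on real dermoscopy data.

## Desk-scale study conditions

The full-size network (9.4 M parameters, 224 px inputs, 100 epochs) is not
trainable in a test suite. The behavioral tests therefore run a
width-multiplier 1/8 network on 64 × 64 images — the identical topology
(33 convolutions, 4 stages, 113 layers) at 1/64 the compute — with
learning rate 0.01, batch size 32 and 15 (learning property) or 12
(bias-mitigation property) epochs. The learning-rate increase compensates
for the ~100-step training budget; the architecture defaults remain the
reference values.

* **Learning property**: on 200 separable synthetic images the tiny
  network reaches ≥ 95% training accuracy in 15 epochs.
* **Null control**: the same training on labels with *zero* association to
  the truth stays at chance on held-out data. The control labels are an
  exactly balanced relabeling (half of each true class), not a plain
  permutation: a permutation retains ~51% agreement with the truth by
  chance, and the network genuinely generalizes that leaked signal (we
  measured clean-test accuracy 0.70 from a 51%-agreement shuffle whose
  training accuracy never left 0.52), which would make the "no
  generalization" check fail for the wrong reason. Because a weakly
  trained network's decision axis can align with the dominant brightness
  direction with arbitrary sign, per-seed control accuracies scatter
  symmetrically around chance; the check is one-sided above, as the claim
  ("does not exceed chance beyond sampling noise") requires.
* **Bias mitigation**: source A couples the vignette to malignancy
  (p = 0.9 vs 0.1; phi ≈ 0.8), source B anti-couples it. A network trained
  on A alone concentrates Grad-CAM mass on the vignette annulus and loses
  accuracy on confound-free images; training on the pooled A ∪ B (where
  the artifact carries no net label information) moves saliency off the
  ring and restores clean-test accuracy. The saliency audit reads the
  stage-3 concatenation output: at 64 px the stage-4 map is 4 × 4, too
  coarse to localize the annulus, while stage 3 (8 × 8) resolves it; both
  deep stages show the effect in the same direction.

  An instructive asymmetry appears between the two biased sources. The
  aligned source (vignette on malignant) reinforces the global-darkness
  cue that already separates the classes, so its model adopts the shortcut
  and degrades on clean data. The anti-aligned source's shortcut
  (vignette on benign) *contradicts* the morphology cue; its model largely
  ignores the artifact and is barely hurt on clean data — pooling can only
  match it on accuracy, though the pooled model is still strictly the
  least vignette-reliant of the three by saliency mass. Confound direction
  relative to the true signal matters, not just confound strength.

## Numerical choices and degenerate inputs

* Stride-2 same-padding convolutions use padding 1, so 224 → 112 exactly;
  shape inference floors the division and validates every concatenation.
* Softmax is computed with the row-max subtracted; probabilities sum to 1
  within 10⁻⁶.
* Ties in argmax prediction resolve to the first class, deterministically.
* An all-zero Grad-CAM map (e.g. a dead ReLU path) is returned as all
  zeros with a flag rather than renormalized; its region mass is defined
  as 0.
* The phi coefficient is computed in double precision (integer contingency
  products overflow 32-bit integers near n ≈ 1500) and defined as 0 with a
  warning when a margin is degenerate.
* Unmapped diagnosis codes (anything outside nv/bkl/df/mel/bcc/ak/akiec —
  e.g. "vasc") raise an error rather than guessing a label.
* Split sizes round half-up on the training side per class; stratification
  requires at least two images per class.

## Known limitations

* The engine is CPU-only and single-threaded apart from BLAS; the
  full-size network is auditable (shapes, parameters, single forward
  passes) but full-scale training is out of reach by design.
* Dataset-level accuracies reported for the reference's four public
  archives require those downloads and GPU-scale training; nothing here
  claims to reproduce them.
* The fused-feature head is a linear probe; no end-to-end fine-tuning of
  fused representations is provided.
* Checkpoints use R serialization with a structural fingerprint; they are
  not interoperable with other frameworks' tensor formats.
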