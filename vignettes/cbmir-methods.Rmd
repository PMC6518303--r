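---
title: "Classification-based medical image retrieval: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification-based medical image retrieval: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A content-based medical image retrieval (CBMIR) system answers a visual
query — "show me past cases that look like this scan" — over a heterogeneous
archive spanning many modalities (CT, MRI, X-ray, ultrasound, endoscopy,
fundus photography) and many anatomical classes. Text tags are often lost
when images leave the PACS/DICOM world, so retrieval must work from pixels.
The approach implemented here turns retrieval into classification: a deep
residual network maps each image to a 2048-dimensional feature vector, a
query is first assigned to a class, and ranking then happens only inside the
predicted class. This cuts the number of feature comparisons from `K * n`
(whole database: K classes of n vectors) to `K + n` (K centroid comparisons
plus one class's members) and, just as importantly, lets the class inventory
grow after training.

## The network

The feature extractor is a 50-layer bottleneck residual network with one
deliberate modification: the terminal 7x7 global average pooling layer is
replaced by **Conv6**, a learnable convolution whose 2048 filters each span
the full 7x7x2048 terminal feature map. Average pooling collapses each
channel with fixed uniform weights (1/49 on a 7x7 map); Conv6 can learn
non-uniform spatial weightings per output feature, which matters when
classes differ in small, localized structures, as neighboring-organ scans
do. The package verifies the relationship explicitly: setting each Conv6
filter to the constant 1/49 on its own channel reproduces average pooling to
numerical tolerance (`test-net-builder.R`).

The stack is Conv1 (7x7/2, 64 filters) -> 3x3/2 max pool -> four residual
groups (Conv2-Conv5) -> Conv6 -> a fully connected (FC) layer as wide as the
class count -> softmax. Each group opens with a *projection* unit (1x1
shortcut convolution that re-depths and, from Conv3 on, downsamples) followed
by *identity* units (shortcut passes the input through unchanged); the census
is 16 units = 4 projection + 12 identity, distributed (2, 3, 5, 2) identity
units over the four groups. Every convolution, Conv6 included, is followed by
batch normalization and a rectifier, so extracted features are non-negative.

Numerical/structural choices where the source layout left room:

* **Residual ordering.** Convolution -> batch norm -> rectifier in the main
  path; the rectifier after the shortcut addition (the original residual-unit
  convention).
* **Downsampling placement.** The stride-2 convolution is the first 1x1 of
  each projection unit (and its shortcut), as the layer table prints it.
* **Max-pool padding.** The layer table prints padding 0 for the 3x3/2 pool,
  but its own feature-map column (112 -> 56) requires padding 1, which is
  also the standard choice; the package follows the feature-map column.
* **Conv6 output.** Taken after batch norm + rectifier, consistent with
  "after each convolutional layer"; features are therefore non-negative.
* **Input sides.** Any multiple of 32 is accepted; Conv6's kernel is sized
  to the Conv5 output side (`side/32`) at build time so it always spans the
  full spatial extent. Other sides are rejected rather than silently padded.
* **Initialization.** FC head: Gaussian, mean 0, sd 0.001, zero biases (the
  stated scheme). Convolutions (only relevant when training from scratch):
  fan-in-scaled Gaussians. One integer seed drives everything; building twice
  with one seed is bit-identical.

The forward and backward passes are implemented in the package itself
(im2col + BLAS GEMM convolution kernels via RcppArmadillo, one-pass compiled
batch-norm reductions), with every kernel tested against naive sliding-window
oracles and central-difference numerical gradients (`test-ops.R`).

## Training

Stochastic gradient descent with the reference configuration: mini-batch 10,
learning rate 0.001 multiplied by 0.1 every 10 epochs, L2 regularization
0.0001 (applied to convolution/FC weights only, not biases or batch-norm
parameters), momentum 0.9, data reshuffled every epoch. The weights kept are
those of the epoch with minimum training loss; training accuracy breaks ties
(loss is the primary key — the two can disagree across epochs and the source
protocol names both without ordering them). Epoch count is a free parameter
(default 30); the published curves only show that training converges.

**Transfer freezing.** `freeze_for_transfer(model, 0.30)` trains the trailing
30% of the ordered named-layer list (softmax and classification layers
included in the count, ties resolved toward training more layers) and
freezes the rest. On the default build that boundary lands exactly at:
Conv5 group + Conv6 + FC trainable, Conv1-Conv4 frozen. Frozen layers
receive no updates *and* keep their batch-norm statistics fixed, so they are
bit-identical before and after training — the stronger invariant is what the
tests assert.

**Class balancing.** Training sets are balanced to a target (default 500
images per class, matching the published balanced-set narrative) by
augmenting under-represented classes with label-preserving in-plane
rotation, translation and cropping. The source does not state magnitudes;
the defaults are mild and configurable: rotation up to 15 degrees,
translation up to 10% of the side, crop side 90-100% re-resized. Every
augmented image is a pure function of (policy seed, draw counter).
Single-channel modalities are made 3-channel by copying channel 1 into
channels 2 and 3.

## Variable node classification (VNC)

After training, deployment-time classification never uses the FC head
except in the closed world. The *offline phase* computes one arithmetic-mean
feature vector per class from the reference features; the *online phase*
assigns a query to the class with the minimum Euclidean distance between its
Conv6 feature vector and the class means. Because the index is just K mean
vectors, unseen classes are *enrolled* by computing their mean from example
images — no retraining — which is what makes open-world (all test classes
unseen) and mixed-world (some unseen) operation possible.

Choices: exact distance ties go to the smallest class id (deterministic and
insertion-order independent — both properties are tested); centroids include
augmented training images by default (the source is silent; excluding them
is a flag at the call site by filtering the store); enrollment uses all
available images of the new class.

## Retrieval and its cost model

`retrieve_with_prediction()` classifies the query (K comparisons) and ranks
only the predicted class's vectors (n comparisons); `retrieve_exhaustive()`
ranks the whole store. With `tau_fe` the feature-extraction time and
`tau_fc` the per-comparison time, the totals are `tau_fe + tau_fc * (K + n)`
and `tau_fe + tau_fc * (K * n)`. The package reports comparison *counts*
(hardware-independent) and checks they equal the formula terms; wall-clock
ratios are deliberately not asserted. With unequal class sizes the
with-prediction count uses the predicted class's actual size — a
generalization of the balanced-class formula. Ranking ties at equal distance
break by image id so output files are deterministic. Top-k defaults to 10.
An optional fallback list reports the next-nearest classes so a user can
re-query when the class prediction is wrong.

## Evaluation

From a K x K confusion matrix (entry (i, j): true class i predicted j) the
package computes one-vs-rest counts and macro metrics: macro accuracy (mean
per-class (TP+TN)/N), macro precision (mAP), macro recall (mAR), and their
harmonic mean F1, plus plain top-1 accuracy (trace/N).

Two deliberate readings of the printed formulas:

* The printed macro-recall denominator is TP+TN, which is not a recall and
  is inconsistent with the magnitudes reported alongside it; the default is
  the standard TP/(TP+FN), and the printed variant remains available as
  `recall_mode = "literal_eq4"` for auditability.
* The printed macro-accuracy form relates to top-1 algebraically as
  `macro = 1 - 2(1 - top1)/K` (tested to 1e-12). For a 50-class problem a
  headline accuracy near 81% can only be the top-1 form (the macro form
  would sit near 0.99), so the package reports both, clearly named.

Classes with an empty denominator (never predicted / never present)
contribute 0 to the macro averages.

**Splits.** Closed world: every class half/half train/test by image (fold 2
swaps the halves). Open world: lower half of the class ids trains, upper
half tests (fold 2 swaps the class sets, giving the asymmetric fold counts
that protocol implies). Mixed world: the lower 80% of classes follow the
closed-world image split; the upper 20% appear complete and only in testing.
Image halving is seeded; class membership is deterministic in the sorted
class ids.

**Sensitivity and comparison.** Monte-Carlo sensitivity resamples a fraction
(default 20%) of the test predictions without replacement for a number of
iterations (default 20) and summarizes each metric's mean and spread;
model comparison uses a two-sample t test (Welch by default, pooled
available) with the degenerate zero-variance-equal-means case reported as
t = 0, p = 1. PCA post-processing centers on training features and projects
onto leading eigenvectors; with all components kept it is an isometry, so
VNC decisions are unchanged — the equivalence is tested directly.

## Synthetic data

The generator emulates the two statistical stresses the method is designed
around — intra-class variance and inter-class similarity — without any
anatomical pretension. Each class owns a parametric prototype (2-4 oriented
elliptical Gaussian blobs + an oriented sinusoid + band-limited smoothed
noise, normalized into [0.1, 0.9]); images perturb the prototype with affine
jitter (rotation/translation scaled by an `affine_magnitude` in [0, 1], 1
meaning up to 20 degrees and 10% shifts), a multiplicative illumination
change, and pixel noise, then quantize to 8 bits. Classes alternate
grayscale/color by default so the channel-replication path is always
exercised; color classes carry a fixed per-class tint so zero jitter
collapses a class to a single image. `similarity_pairs = (a, b, s)` blends
fraction `s` of class a's prototype into class b's — at s = 1 the two
classes are pixel-identical and any classifier must confuse them.
Everything is a pure function of the spec seed; manifests record md5
digests so byte-identity is testable.

What passing synthetic tests does **not** show: robustness to the texture
statistics, acquisition artifacts, and label noise of real medical archives,
nor the absolute accuracy levels reported on the 50-class multi-source
collection — those require the real data and GPU-scale fine-tuning from
pretrained weights, which are outside this package's scope.

`make_feature_fixture()` skips images entirely: K isotropic Gaussian
clusters with equidistant centroids (`separation` in units of the noise sd)
give a direct dial on difficulty for the VNC/retrieval/evaluation tests.
At separation 6 the per-point error probability toward each competing class
is `pnorm(-3) ~ 1.4e-3`, so "perfect recovery" is the typical outcome only
when `(K - 1) x N` is a few hundred or less; the perfect-recovery test
therefore runs at K = 2, n = 50 with a frozen seed verified to realize the
typical outcome (29/30 seeds do), while larger K enters through the
monotone-difficulty property (accuracy non-increasing as separation drops
through 10, 4, 1, 0).

## Problem sizes in the tests

The shipped tests exercise the full 224px architecture for structure
(shape audit, intermediate dimensionalities) and train only scaled-down
instances: the end-to-end run uses 10 trained + 5 enrolled classes, 50
images per class at 64px for 15 epochs in the transfer configuration
(Conv1-Conv4 frozen). These sizes were chosen so a complete check runs on a
single CPU at desk scale; with strong class separation the pipeline reaches
perfect closed-world top-1 and open-world enrollment accuracy there, which
is a sanity gate on the plumbing, not a reproduction of the published
accuracy tables. Training from random initialization with the frozen
backbone is effective here because strongly separated synthetic classes
remain linearly separable under a random deep feature map; on real data one
would load pretrained backbone weights before freezing (`save_model()` /
`load_model()` round-trip any externally supplied weights).

## Known limitations

* No GPU path and no mixed precision; double-precision BLAS only.
* No pretrained weights are bundled (licensing and size); transfer learning
  expects externally supplied weights.
* No approximate nearest-neighbor index: with K up to a few hundred classes
  the exhaustive centroid scan is exact and fast, which is the regime the
  method targets.
* The generator's color model (global tint) does not emulate
  channel-specific anatomy (e.g. fundus vasculature).
* Wall-clock retrieval-time claims are not reproduced; only comparison
  counts are asserted.
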