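---
title: "Attention-based metric learning for radiograph re-identification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based metric learning for radiograph re-identification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A frontal chest radiograph carries a stable anatomical signature — rib
geometry, thorax outline, cardiac silhouette, clavicles, spine — that
persists across a patient's repeat examinations. `sranet` treats that
signature as a biometric: it learns an embedding function $f(\cdot)$ mapping
an image to a fixed-length vector such that images of the same person lie
close in Euclidean distance and images of different people lie far apart.
Two downstream tasks follow directly:

* **identification** (one-to-many): rank a gallery of enrolled embeddings by
  distance to a query and return the top-$k$ matches;
* **verification** (one-to-one): declare two images the same person iff
  their embedding distance falls below a threshold.

Because both tasks operate purely on stored embeddings, enrolling a new
person never requires retraining — their images are embedded once and
appended to the gallery.

## The embedding generator

The generator is a convolutional network with the fixed layer order

> backbone feature map → self-residual attention block 1 →
> self-residual attention block 2 → attention block →
> reverse attention block → flatten → dense (Softplus) → dense (linear)

yielding a 256-dimensional embedding under the default configuration.

### Attention arithmetic

All three blocks are built from two multiplicative gates.

**Channel attention.** For a feature map $X \in \mathbb{R}^{H\times W\times
C}$, each channel is pooled to its global average
$\mathrm{GAP}(X)_k = \frac{1}{HW}\sum_{i,j} X_{ijk}$ and its global maximum
$\mathrm{GMP}(X)_k = \max_{i,j} X_{ijk}$. The concatenated $2C$-vector
passes through a single dense layer and a logistic sigmoid,

$$\mathrm{CA}(X) = \sigma\!\big(\mathrm{Dense}[\mathrm{GAP}(X),
\mathrm{GMP}(X)]\big) \in (0,1)^C,$$

and the map is reweighted channelwise: $X \odot \mathrm{CA}(X)$. The gate is
a single affine map with no bottleneck/reduction ratio — the minimal dense
gate consistent with the architecture.

**Spatial attention.** The map is reduced across channels at each location
(mean and max), the two pooled $H\times W$ maps are concatenated and passed
through a $7\times 7$ convolution with a sigmoid,

$$\mathrm{SA}(X) = \sigma\!\big(\mathrm{Conv}_{7\times 7}[\mathrm{AvgPool}(X),
\mathrm{MaxPool}(X)]\big) \in (0,1)^{H\times W},$$

and broadcast-multiplied across channels.

**Self-residual attention block (SRAB).** A $3\times 3$ convolution (stride
1, shape-preserving padding), batch normalisation and a Softplus
activation, then the channel gate followed by the spatial gate, plus a
residual shortcut from the block input — projected by a $1\times 1$
convolution only when the channel counts differ, identity otherwise:

$$X_\text{out} = \mathrm{SA\text{-}gate}\big(\mathrm{CA\text{-}gate}(
\mathrm{Softplus}(\mathrm{BN}(\mathrm{Conv}(X))))\big) + X_\text{res}.$$

**Attention block.** The two gates applied directly to the input — no
convolutional preamble and no residual; the shape is preserved.

**Reverse attention block.** Conv → batch norm → Softplus followed by a
channel gate only. Taken literally this is a second channel attention on a
convolved input; the "reverse" reading (emphasising what previous gates
suppressed) has no distinct arithmetic of its own, so the literal form is
the default and a `complement_gate` option gates with $1-w$ instead of $w$
for users who want the complementary behaviour. The option exists because
the two readings genuinely differ and the choice is not decidable from the
architecture description alone.

The kernel sizes (3 for block preambles, 7 for the spatial gate, 1 for the
residual projection) follow the conventions of residual-network and
convolutional-attention architectures; the blocks themselves do not fix
them.

### Backbones

* `resnet50` (default): the standard 50-layer residual network truncated at
  its final convolutional feature map (stem $7\times7/2$ + $3\times3/2$ max
  pool; bottleneck stages of depth 3/4/6/3), 2048 channels at $1/32$
  resolution. Weights are He-initialised. **There is no bundled pretrained
  state and no download mechanism**; `backbone_pretrained = TRUE` requires
  an explicit `weights_file` produced by `save_model()`. Fine-tuning is
  end-to-end: no layer is frozen.
* `tiny`: four $3\times3$ convolutions (three at stride 2), 32 output
  channels at $1/8$ resolution — the CPU-scale backbone used throughout the
  package's tests and benchmark.

The head flattens the final map, applies a hidden dense layer (512 units,
Softplus) and a linear output layer. Embeddings are *not* L2-normalised;
all distances are raw Euclidean.

### Siamese training with triplet loss

Three branches (anchor $A$, positive $P$ — same patient, negative $N$ —
different patient) share one embedding generator; the distance layer
computes $D_{AP} = \lVert E_A - E_P\rVert_2$ and
$D_{AN} = \lVert E_A - E_N\rVert_2$ and the loss is the hinge

$$L(A,P,N) = \max(0,\; D_{AP} - D_{AN} + \text{margin}),$$

with margin defaulting to 0.5. Optimisation uses Adam (default learning
rate $10^{-4}$, triplet batch 16). Each batch stacks all $3B$ images of its
$B$ triplets into one forward pass so the batch-normalisation statistics
see all branches; backpropagation runs through the entire network,
including the backbone. All layer gradients are verified against central
finite differences in the test suite (relative error below $10^{-6}$).

### Data preparation rules

* Images are read as 8-bit PNG, converted to three identical channels when
  grayscale, resized to $200\times200$ (bilinear, antialiased) and scaled
  to $[0,1]$.
* Patients with fewer than two images are excluded — no positive pair
  exists for them.
* Per sampling pass, each patient contributes one randomly chosen anchor,
  a positive drawn uniformly from the patient's remaining images and a
  negative drawn uniformly from another patient's images.
* By default `train_triplet_model()` reuses one fixed, seed-reproducible
  triplet list every epoch; `resample_each_epoch = TRUE` draws a fresh list
  per epoch. Resampling is the right choice for small cohorts (see the
  benchmark section).

## Synthetic radiograph phantoms

The generator (`identity_phantom()`, `acquisition_params()`,
`render_radiograph()`, `generate_dataset()`) exists so every pipeline stage
is testable without any external imaging data. It realises exactly the
statistical structure the method assumes:

* **identity-stable anatomy**: per-patient geometric parameters — thorax
  ellipse semi-axes, rib count/spacing/curvature/width, cardiac silhouette
  width and offset, clavicle angle, spine offset — drawn once per identity
  from fixed ranges chosen so that every phantom renders in frame and two
  random identities essentially always differ;
* **acquisition variation**: per-image rotation (±3°), translation (±3% of
  the field), brightness (±0.06) and contrast (±10%) jitter, plus additive
  Gaussian pixel noise with standard deviation 0.04 — about ten grey levels
  of an 8-bit detector, a realistic noise floor for screening radiographs.

Rendering is closed-form geometry evaluated on the transformed coordinate
grid, so an (identity seed, acquisition seed) pair reproduces an image
bit-exactly. Under these defaults the identity signal is strong but not
trivial: same-identity renders correlate around 0.93 while
different-identity pairs sit near 0.67, and a raw-pixel nearest-centroid
classifier is already well above chance. That is deliberate — the phantom
suite validates the *machinery* (architecture, gradients, sampling,
retrieval, calibration), not clinical realism. Real radiographs add
pathology, positioning and device variation, occlusion and longitudinal
change that the phantoms do not model, so passing the synthetic benchmark
demonstrates correctness of the implementation, not expected field
accuracy.

## The scaled benchmark

`benchmark_reid()` is the package's study: 20 synthetic identities × 5
images at 64×64 pixels, tiny backbone (32-dimensional embedding), Adam at
$10^{-3}$, margin 0.5, 30 epochs of 200 triplets resampled each epoch,
about three minutes of single-threaded CPU. It evaluates the trained model
and the identically initialised untrained model on the same protocol:
every image queries the gallery of the remaining 99 (the query itself is
excluded — self-matching would trivialise the metric), and 200 labelled
pairs are split evenly into a calibration half (threshold selection) and a
held-out half (reported metrics).

Two training-methodology choices matter here and were made for stated
reasons, not tuned against the evaluation:

* **learning rate $10^{-3}$** rather than the full-scale $10^{-4}$: with
  only ~100 parameters updates per epoch on a tiny network, the larger step
  size is the standard small-problem choice;
* **per-epoch triplet resampling**: on a 100-image cohort a fixed triplet
  list saturates the hinge within a few epochs while most same-identity
  pairs have never been seen, so the embedding geometry stops improving
  long before it generalises across the cohort. Fresh triplets keep the
  constraint set moving. (The full-scale default remains a fixed list,
  where tens of thousands of patients make saturation a non-issue.)

Typical behaviour (seed 1): the trained model reaches top-1 identification
1.00 and verification accuracy 0.95 on the held-out pairs, while the
untrained architecture scores 0.52 and 0.76 — the trained ≫ untrained
pattern the architecture is designed to produce. Mean anchor–positive
distance falls well below mean anchor–negative distance (≈3.4 vs ≈9.0
after training).

## Verification threshold calibration

No principled threshold comes with raw Euclidean distances, so
`calibrate_threshold()` selects it empirically: candidate thresholds are
the midpoints between consecutive sorted observed distances (plus one
candidate below and one above all of them); the accuracy-maximising
candidate wins, ties going to the smallest threshold. The equal-error-rate
operating point (|false-accept − false-reject| minimised) is reported
alongside for users who prefer a balanced operating point. Calibration and
evaluation always use disjoint pair sets.

## Numerical choices and degenerate inputs

* Batch normalisation uses $\varepsilon = 10^{-3}$; running statistics
  (momentum 0.9) are used in inference mode, and a freshly built model's
  running statistics are mean 0 / variance 1.
* Gate logits are clamped to ±30 before the sigmoid so gate weights stay
  strictly inside $(0,1)$ in double precision; Softplus is evaluated in its
  overflow-safe form $\max(x,0) + \log(1+e^{-|x|})$.
* Distance gradients guard against the non-differentiable zero-distance
  case with a $10^{-12}$ floor.
* Spatial/channel max-pooling breaks ties by first index; retrieval breaks
  distance ties lexicographically by image id — both make runs bit-for-bit
  reproducible.
* Non-finite intermediates in the attention blocks raise an error naming
  the stage; non-finite training loss aborts with a diagnostic.
* Empty feature maps, metadata without the required columns, single-patient
  triplet requests, non-positive thresholds and single-class calibration
  sets are all rejected with explicit errors.

## Known limitations

* Without pretrained backbone weights the full-scale `resnet50`
  configuration starts from random initialisation; reaching the accuracy
  regime reported for large public chest X-ray collections requires those
  collections and GPU-scale training, which is outside this package's
  scope. The benchmark demonstrates the qualitative trained-vs-untrained
  contrast at desk scale.
* The phantom generator does not model pathology, projection differences
  (PA vs AP), device heterogeneity or longitudinal anatomical change.
* Training is single-threaded CPU R; it is adequate for the tiny backbone
  and correctness work, not for large-scale experiments.
* The reverse attention block's literal form duplicates channel attention;
  whether its complement mode is preferable on real data is an open
  empirical question the package exposes but does not answer.
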