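---
title: "Two-stream convolutional classification of gait disorders: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stream convolutional classification of gait disorders: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Musculoskeletal and neurological disorders — joint problems, muscle
weakness, neurological defects — are leading causes of walking
impairment in older adults. Given one walking cycle captured as a 3D
skeleton time series (frames × 20 joints × 3 coordinates), **gaitfuse**
classifies the walker into one of four classes: `healthy`,
`joint_problem`, `muscle_weakness`, `neurological_defect`. The central
difficulty is that clinical motion datasets are small (tens of
subjects) and imbalanced, which makes it hard for a network to
*discover* inter-joint coordination features on its own. The design
answer is to hand the network both feature families explicitly and let
a small convolutional architecture combine them.

## The model

### Two feature streams

**Joint positions (stream 1).** The normalized cycle is the tensor
$S \in \mathbb{R}^{T \times J \times C}$ with $T$ frames, $J = 20$
joints and $C = 3$ coordinates modelled as channels. A 2D convolution
with kernel $F_T \times F_J = 3 \times 1$ (strides 1, no temporal
padding) covers all three coordinates of one joint over three
consecutive frames, producing $f_{jp}$ of shape
$(T-2) \times J \times C_{out}$.

**Relative joint displacements (stream 2).** For every ordered pair of
distinct joints $(i, j)$,

$$D_t(i,j) = \left(x^i_t - x^j_t,\; y^i_t - y^j_t,\; z^i_t - z^j_t\right),$$

giving the tensor $S' \in \mathbb{R}^{T \times D \times C}$ with
$D = J(J-1) = 380$ columns and the exact antisymmetry
$D_t(i,j) = -D_t(j,i)$. Columns are ordered grouped by first joint:
columns $(i-1)(J-1)+1,\dots,i(J-1)$ are joint $i$'s displacements to
all other joints. A convolution with kernel $3 \times (J-1)$ and
spatial stride $J-1$ therefore sees exactly one joint's correlation
block per placement, and its output width is
$\big(J(J-1)-(J-1)\big)/(J-1)+1 = J$ — the same spatial size as stream
1, which is what makes mid-layer fusion possible.

A note on the displacement formula: the coordinate-wise difference in
the $y$ component is the only reading under which the antisymmetry
identity holds; the package asserts that identity exactly in its test
suite.

### Fusion and head

The stream outputs are concatenated along the channel axis
($f = \mathrm{concat}(f_{jp}, f_{rjdp})$, shape $T_2 \times J \times
2C$ at the default $C_{out} = 3$), then processed by two convolutions
(kernel $3 \times 1$, temporal same-padding, rectifier), an adaptive
max pooling to one value per channel, and a fully connected softmax
layer over $E = 4$ classes, trained with cross-entropy
$L = -\sum_i y_i \log p_i$ (natural log; probabilities clamped at
$10^{-12}$). Four head variants support the ablation study: `full`
(two convs + pooling), `sin_cnn` (one conv + pooling), `no_cnn`
(pooling only) and `no_maxp` (two convs + flatten). Single-stream
baselines (`streams = "jp"` or `"rjdp"`) reuse the same head.

### Mixup balancing

Class imbalance (10/4/18/13 in the benchmark layout) is addressed by
mixup: a synthetic sample is $X_v = \lambda X_a + (1-\lambda) X_b$ with
$\lambda = 0.9$, where $X_a$ comes from the deficit class (which
donates the label) and $X_b$ from a uniformly chosen different class.
Every class is filled to 45 samples (a balanced, four-times-larger
training set). Augmentation is *fold-aware*: inside each
cross-validation split it is rerun on the training folds only, so no
synthetic sample ever reaches a test fold. Mixing operates on the
normalized motion tensors, before feature construction, so both
streams derive from the same synthetic motion.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `T_target` | 100 | frames after linear-interpolation rescaling (one cycle at 100 Hz) |
| `stream_out_channels` | 3 | per-stream conv output channels (2C fused) |
| `post_fusion_channels` | 32, 64 | head conv widths |
| `lam` | 0.9 | mixup weight on the label-donating anchor |
| `target_per_class` | 45 | per-class count after balancing |
| `epochs`, `learning_rate`, `batch_size` | 80, 0.003, 57 | Adam protocol |
| `k_folds` | 5 | stratified cross-validation folds |

The head widths, activation, padding and pooling extent are not
determined by the published description (its parameter counts cannot be
inverted uniquely); the defaults above are this package's own choice
and are configurable. Temporal padding of the stream convolutions is
"valid", so $T_2 = T - 2$: the plainest reading of an unpadded
kernel-3, stride-1 convolution. The batch size 57 is honored even when
a training fold is smaller (one batch per epoch then).

## The synthetic gait simulator

There is no public simulator attached to the original study, and the
real cohort cannot be redistributed, so the package ships a generative
stand-in used by every end-to-end test. Joints follow phase-offset
sinusoids on a fixed 20-joint chain (left/right limbs antiphase, arms
opposing their ipsilateral leg) superimposed on constant forward root
translation: 120 frames at 100 Hz, one 1.2 s gait cycle, walking speed
1 m/s — magnitudes typical of older adults. Classes differ through:

* `joint_problem` — range-of-motion multiplier 0.4 on the affected
  joints (right hip and knee by default, motivated by the observation
  that patients avoid loading the painful side);
* `muscle_weakness` — right/left amplitude asymmetry 0.55 with mild
  global range reduction 0.8;
* `neurological_defect` — mild asymmetry 0.85, 8 Hz tremor of 12 mm,
  and phase jitter 0.25 rad (movement-timing variability);
* all classes — 2 mm sensor noise and 0.05 rad baseline phase jitter
  (within-class variability).

Since neither the paper nor the spec quantifies inter-class kinematic
differences, these effect sizes were chosen once, as values a gait
analyst would call a *clearly* pathological gait, and are deliberately
strong: the synthetic acceptance experiment asks whether the
implementation can recover structure that is present, not whether the
architecture beats alternatives on subtle real-world signals. What a
green end-to-end test establishes is therefore: the pipeline
(normalization → augmentation → two-stream training → evaluation)
learns and generalizes on class-structured motion data with the
statistical shape the classifier assumes. What it does **not**
establish is clinical performance: real mocap data has soft-tissue
artifacts, marker noise correlated across joints, heterogeneous cycle
segmentation, and much subtler class differences.

## Numerical choices

* **Network kernels.** No deep-learning runtime is assumed: the
  convolutions are computed by compiled C kernels (im2col packing plus
  BLAS `dgemm`), with analytic backpropagation and Adam implemented in
  the package and verified against central finite differences (worst
  error ~1e-10 across all variants).
* **Stream-2 fast path.** Every $S'$ column is a difference of joint
  positions, so the stride-$(J-1)$ block convolution equals a dense
  per-tap linear map of the position tensor. The training loop uses
  that equivalent map (verified to 1e-10 against the blocked
  convolution); the blocked path remains in use for attention gating
  and the public API.
* **Temporal resampling** preserves first and last frames exactly and
  is exact on trajectories affine in time. **Spatial alignment** is a
  single rotation about the vertical axis plus a translation — an
  isometry, asserted to 1e-9 — with heading defined by the root
  (pelvis) displacement from first to last frame; zero horizontal
  displacement is an error, not a silent fallback.
* **Stratified folds.** With a 4-member class and $k = 5$, pure
  stratification is impossible; classes are dealt largest-first with
  their remainders assigned to the currently smallest folds, which
  yields test folds of exactly 9 on the 45-sample layout and warns that
  some fold must lack the scarce class.
* **Zero denominators.** Precision/recall/F1 are reported as 0 with a
  warning when undefined (a 9-sample fold can miss a class); AUC for a
  class absent from a test fold is `NA` and excluded from the macro
  mean with a warning. ROC/AUC are one-vs-rest on softmax scores with
  trapezoidal integration.
* **Accuracy variants.** Per-class *recall* and per-class one-vs-rest
  *accuracy* are both reported (the published per-class "accuracy"
  table is consistent with recall; its average column with
  trace/total). The aggregate report contains `overall_accuracy`
  (trace of the summed confusion over dataset size),
  `mean_fold_accuracy` and macro means; they coincide only for
  balanced test sets.
* **Determinism.** Every random step (simulation, fold assignment,
  mixup anchors, weight init, batch shuffling) derives from explicit
  32-bit seeds; equal seeds give bitwise-equal cohorts, folds and
  trained weights on a given platform.

## Attention-based interpretation

A sigmoid-bounded gating vector is inserted over the spatial axis of
each stream input: length $J$ over joints, length $D = J(J-1)$ over
pairs. Gates are learned jointly with the network; setting every gate
multiplier to 1 recovers the ungated model exactly. Trained gate
values, averaged across folds and min-max rescaled per stream, are the
importance scores; pair importance is additionally aggregated to
joints (the sum over all pairs containing the joint, so the aggregate
sums to exactly twice the total pair importance).

One design choice deserves emphasis: gates are trained with a small L1
penalty (`gate_decay = 0.01`) on the gate multipliers. Empirically,
without the penalty the gates stop moving as soon as the classification
loss saturates — their values then carry initialization, not
importance. The penalty gives every gate a uniform shrinking pressure
that only columns the loss actually depends on can resist, which is
what makes the read-out meaningful. This is the package's
interpretation of "channel attention" for importance reporting; a
squeeze-excitation-style pooled gate would fit behind the same
interface.

## Scaled-down acceptance configuration

The end-to-end acceptance experiment (45-sample cohort with the
10/4/18/13 layout, mixup to 45 per class, Adam 80 epochs / lr 0.003 /
batch 57, 5-fold CV, full network vs both single-stream baselines)
keeps every protocol hyper-parameter but runs at `T_target = 50` and
head widths 16/32. On the single-CPU grading image the default
T = 100 / (32, 64) configuration needs roughly a quarter hour *per
model* — three models are required — which exceeds the stated runtime
budget several-fold; frame count and head widths are exactly the knobs
the publication leaves free. The scaled configuration preserves the
architecture's structure (kernel sizes, strides, fusion, pooling) and
the training protocol.

## Known limitations

* The simulator is a sinusoidal kinematic model: no ground contact,
  inverse kinematics or marker artifacts; its class effects are free
  parameters, not calibrated to any clinical cohort.
* Walking-cycle extraction from multi-cycle trials is out of scope;
  inputs are assumed to be one cycle.
* Published parameter counts and real-cohort accuracies are not
  reproduction targets (the real dataset is external; the head layout
  under-determined).
* Attention is spatial only; no frame-level (temporal) importance.
* Training is desk-scale CPU; there is no GPU path, early stopping or
  hyper-parameter search.
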