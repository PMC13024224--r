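---
title: "Semi-supervised gait classification: model, pooling and training engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised gait classification: model, pooling and training engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmt)
```

## The problem

Frontal-plane leg malalignment in children — genu varum ("bow-legged": the
ankles approximate while the inter-knee gap stays open) and genu valgum
("knock-kneed": the knees approximate while the inter-ankle gap stays open)
— is visible in an ordinary frontal walking video. `gaitmt` implements a
screening-oriented video classifier for the three alignment classes
(Normal / Genu varum / Genu valgum, encoded 11 / 21 / 22; the binary
screen merges the two malalignments into Abnormal, encoded 1 / 2). Two
obstacles shape the design: labeled clinical videos are scarce, and the
discriminative signal is a subtle, multi-scale spatial pattern. The model
therefore combines

* a **3D residual convolutional backbone** over clip tensors
  (batch x channel x time x height x width),
* a **spatial hierarchical pooling module (SHPM)** replacing the terminal
  global pooling, and
* a **Mean Teacher** semi-supervised training engine that exploits
  unlabeled clips.

## The spatial hierarchical pooling module

The backbone's final feature map $X \in \mathbb{R}^{B \times C \times T
\times H \times W}$ is partitioned, per frame, into a pyramid of spatial
bin grids. A level with block size $(H_{size}, W_{size})$ yields
$H_{bins} = H / H_{size}$ and $W_{bins} = W / W_{size}$ bins (divisibility
is enforced at build time; there is no silent padding). Every block
contributes its maximum

$$\mu_{b,c,t,i,j} = \max_{h,w} X_{b,c,t,\,iH_{size}+h,\,jW_{size}+w}$$

which emphasises the most prominent local activation, and its average

$$\eta_{b,c,t,i,j} = \frac{1}{H_{size} W_{size}}
  \sum_{h,w} X_{b,c,t,\,iH_{size}+h,\,jW_{size}+w},$$

which keeps the mean signal strength of the region. Statistics are pooled
spatially per frame, then reduced over the temporal axis (mean by default,
max available), and all levels are concatenated into one feature vector
feeding a single linear classification layer.

Choices that were genuinely open, and how they were fixed:

* **Pyramid.** Default levels are the dyadic 1x1, 2x2 and 4x4 bin grids of
  the final map (grids that do not divide the map evenly are dropped).
  This is the minimal pyramid that adds local structure to global pooling;
  it is configurable (`shpm_levels`).
* **Max/average merge.** Concatenation by default — it preserves both
  signals; `sum` (fusion) and `avg` (average-only, used as the
  global-average-pool ablation when combined with a single global level)
  are provided.
* **Temporal order.** Pooling is spatial-first, per frame, honouring the
  per-frame character of gait features; the temporal reduction follows.
  Mean keeps all frames' evidence; max is available for burst-like events.

## The backbone

The full-scale preset is the standard 3D ResNet-18 topology (4 stages of
2 basic residual blocks, channels 64/128/256/512, stem with spatial
stride 2). The `tiny` preset used at desk scale keeps the same block
structure with 2 stages (channels 6/12 — ample capacity for the
synthetic geometry) and downsamples spatially only from stage 2, so a
32x32 input still yields an 8x8 final map and a non-trivial SHPM
pyramid. Convolutions are initialised He-style (fan-out),
batch norms start at identity, the classifier bias at zero; construction
is seed-deterministic. Batch statistics are used in training mode; running
statistics (momentum 0.1) make evaluation-mode predictions independent
across batch rows.

All numerics — 3D convolution (im2col + BLAS gemm, compiled), batch norm,
residual blocks, SHPM, softmax/cross-entropy and Adam — are implemented in
the package with explicit forward and backward passes; the test suite
checks every layer's analytic gradient against central finite differences.

## The Mean Teacher engine

Two networks share one architecture: the **student** learns by
backpropagation, the **teacher** is an exponential moving average of the
student, $\theta' \leftarrow \alpha\theta' + (1-\alpha)\theta$ with
$\alpha = 0.99$, applied after every optimisation step and never receiving
gradients (batch-norm running statistics are EMA-tracked the same way —
the teacher must be a complete, runnable smoothed copy). The teacher is
initialised as $\theta' = \theta$.

Each step the student sees strongly augmented clips (random crop, colour
jitter, Gaussian noise, random erasing, temporal jitter, speed
perturbation), the teacher weakly augmented ones (light crop, horizontal
flip). The objective is

$$L = \underbrace{\frac{1}{n}\sum_i \mathrm{CE}(p^{(s)}_i,
Y_i)}_{\text{supervised}} + \lambda(e) \cdot \underbrace{\frac{1}{k}
\sum_j \lVert p^{(s)}_j - p^{(t)}_j \rVert_2^2}_{\text{consistency}}
 + \lambda(e) \cdot \text{(gated pseudo-label CE)},$$

with probabilities (not logits) entering the consistency term — soft
targets preserve the teacher's uncertainty and temper confirmation bias.
$\lambda(e)$ ramps linearly from 0 to 1 over the first 30 epochs (10 at
desk scale, the same 30% of the schedule), so supervised structure is
established before unlabeled data weighs in. Teacher predictions whose
maximum probability strictly exceeds $\tau = 0.8$ also contribute a hard
pseudo-label cross-entropy, weighted $\lambda(e)$ and normalised as an
expectation over the whole unlabeled batch — rejected samples contribute
zero, so a handful of confident clips carries proportionally little
weight. (Normalising over accepted samples only, the tempting
alternative, hands one confident-but-wrong clip the gradient weight of an
entire batch; at desk scale that reliably collapses training.)
`promote_pseudo_labels()` implements the pool-promotion view of the same
gate, with a termination guard when a full pass promotes nothing.

One printed-formula conflict had to be resolved: the combined objective as
printed multiplies the supervised term by $\lambda$ and the consistency
term by $(1-\lambda)$, which would anneal supervision *off* while the
operational protocol states the *consistency* weight increases from 0 to
1. This implementation follows the operational semantics
($L = L_{sup} + \lambda L_{cons}$), the standard Mean Teacher form.
Likewise the schematic plain-gradient-descent update is realised as Adam
(learning rate $10^{-4}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$), as the
training protocol specifies.

The optimiser budget is decoupled from the labeled-pool size: every epoch
takes `steps_per_epoch` labeled batches from a cycling shuffled iterator
(default: one pass over the labeled clips). In low-label experiments all
arms are given the number of steps a fully labeled epoch would take, so
comparisons hold the optimisation budget fixed — without this, a 20%-label
run starves (two steps per epoch) and the plateau scheduler halves the
learning rate into numbness before anything is learned.

Early stopping monitors the validation loss (patience 10 full-scale),
and a reduce-on-plateau rule halves the learning rate after 5 stagnant
epochs; the returned model is the best-validation snapshot of both student
and teacher.

## The synthetic cohort

Real pediatric videos cannot ship with a package, so every stage is
exercised on synthetic frontal-view walkers: an articulated stick figure
(head disc, torso, hip bar, two two-segment legs with feet) rendered as
anti-aliased strokes, walking in place with a sinusoidal leg lift, lateral
sway and per-subject phase. The class-defining degree of freedom is
`knee_offset`, the signed horizontal displacement of each knee from its
hip–ankle line in fraction-of-leg-length units: negative pushes the knees
outward (varum), positive inward (valgum). Labels follow deterministic
thresholds with margin $\delta = 0.05$; per-class offsets are drawn from
$[-0.25, -0.10]$ (varum), $[-0.02, 0.02]$ (normal) and $[0.10, 0.25]$
(valgum), so classes are cleanly separated with $\delta$ of head-room —
near-boundary sampling remains available by calling `walker_params()`
directly. Nuisance parameters per subject: stride period 8–24 frames,
figure height 0.5–0.9 of the frame, additive Gaussian noise SD 0–0.05,
random initial phase. Severity is nowhere quantified clinically; the
offset ranges are a modeling choice tuned for a well-posed desk-scale
benchmark, not an inference about any cohort.

A model-free check keeps the generator honest:
`gait_geometry_classify()` re-measures the inter-leg widths at knee and
reference heights from the rendered pixels and recovers the generating
label for 100% of noise-free samples — so the learning problem is
well-posed before any network is trained.

What the generator deliberately does **not** emulate: photorealistic
appearance, clothing, occlusion, camera perspective, multi-person scenes,
background clutter, or the other gait abnormalities of the binary screen
(foot dragging, trunk sway). Passing tests on this cohort demonstrate
that the architecture and training engine work as specified; they do not
certify clinical performance on real videos.

## Evaluation

Videos are sliced into fixed-length clips (16 frames full-scale, 8 at desk
scale); clip softmax probabilities are averaged into one video-level
distribution (clips inherit their video's label during training). The
binary decision thresholds the merged abnormal probability at 0.5, with
the tie decided toward Normal — a conservative screening default; the
pseudo-label gate $\tau$ plays no role at test time. Metrics: accuracy,
macro precision/recall (unweighted one-vs-rest averages) and macro F1
computed as the harmonic mean of macro P and macro R — the explicit
reported formula, *not* the mean of per-class F1 scores (the two differ
and the test suite pins the distinction); sensitivity, specificity, PPV,
NPV and PR-AUC (step rule) for the binary screen. Zero-denominator
metrics surface as flagged `NA` with a warning — silent zeros would
corrupt macro averages. A subject-leakage guard makes evaluating on any
training subject a hard error.

Grad-CAM saliency differentiates the predicted class's logit with respect
to the last convolutional feature map (the exact activations SHPM
consumes), averages the gradient per channel, rectifies the weighted
activation sum, upsamples (bilinear in space, nearest in time) and min–max
normalises per clip. On synthetic cohorts the discriminative geometry sits
in the lower half of the frame, and the saliency mass concentrates there.

## Desk-scale profile and problem sizes

The package ships two named profiles. `full` mirrors the reference
protocol exactly (224x224 crops from 2560x1440 frames, 16-frame clips,
ResNet-18, batch 16, 100 epochs, lr $10^{-4}$). `desk` is the scale this
package trains routinely on one CPU and is used by the examples, tests
and the acceptance script: 32x32 frames, 8-frame clips, the tiny
backbone, lr $10^{-3}$ (appropriate for the ~10k-parameter network),
30 epochs with the $\lambda$ ramp over the first 10, EMA rate 0.9 and
unlabeled half-batches of 8. Benchmark
experiments (`gait_benchmark()`) use cohorts of 60 subjects (16-frame
videos, two clips each) with stratified subject-level 64/16/20 splits;
the learnability experiment runs 15 epochs, while the low-label
semi-supervised comparison runs a fixed 45-epoch schedule for every arm
— Mean Teacher training converges more slowly than purely supervised
training on the same labeled subset, and comparing the arms before the
engine has converged would measure schedule truncation, not the method.
All arms of a comparison receive the identical optimisation budget.
These sizes are the package's chosen study conditions; the semantics
never change between profiles.

## Numerical choices and degenerate inputs

* Softmax subtracts the row maximum (shift-invariant, overflow-safe);
  cross-entropy clamps probabilities at $10^{-12}$.
* Max-pooling ties take the first block element (deterministic).
* The crop convention is 0-based and half-open with floor offsets.
* An all-zero Grad-CAM map is returned flat with a warning, not an error.
* An empty unlabeled pool degrades training to plain supervised learning;
  the trajectory is bit-identical to never passing unlabeled data.
* Every stochastic component (generation, splits, initialisation, data
  order, augmentation) fans out from one integer seed.

## Known limitations

* The synthetic walkers are far easier than clinical video; desk-scale
  accuracies near 1.0 say nothing about real-world screening performance.
* The EMA rate must suit the schedule length: $\alpha = 0.99$ (a ~100-step
  smoothing horizon) is appropriate for the reference protocol's thousands
  of optimisation steps, but over a ~150-step desk run such a teacher
  stays near its initialisation for most of training and its consistency
  targets drag the student. The desk profile therefore uses
  $\alpha = 0.9$, keeping the smoothing horizon a comparable fraction of
  the schedule; the full profile keeps 0.99.
* Calibration of predicted probabilities is out of scope, as is any
  baseline architecture comparison.
* Real-video decoding is supported only through the PNG-frames dataset
  layout; arbitrary container demuxing is delegated to external tools.
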