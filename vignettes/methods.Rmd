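---
title: "Methods: dual-pathway recognition of stall postures and behaviors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-pathway recognition of stall postures and behaviors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model, its tunable
parameters, the synthetic data it is validated on, and the design decisions
taken where more than one reasonable choice existed.

## The recognition model

### Label taxonomy and its constraints

Five labels annotate a stalled horse: the postures Standing, Sternal
recumbency, and Lateral recumbency, and the behaviors Eating and Sleeping.
The constraints are structural, not statistical, and the package enforces
them at every boundary (annotation I/O, generation, prediction targets):

* exactly one posture per (video, second, entity);
* Eating only together with Standing (a horse eats off the ground from a
  standing position);
* Sleeping may accompany any posture;
* seven legal posture/behavior combinations exist in total.

### Dual-rate clip sampling

Each annotated second is recognized from a window of `L = 64` frames
centered on that second's first frame. The slow pathway samples the window
with temporal stride 16 (`N_slow = 4` frames) and carries the appearance
channels (`C_slow`, default 64 at full scale, 16 in the `tiny` preset); the
fast pathway samples with stride 2 (`N_fast = 32`) at `beta = 1/8` of the
slow width, so motion is represented densely but cheaply. The identities
`N_slow * 16 = N_fast * 2 = L` and `C_fast = beta * C_slow` (a positive
integer) are validated in `net_config()` rather than assumed.

The window is *centered* on the annotated frame, with out-of-range indices
clamped to the video edges (frame repetition). Centering is a design choice:
the annotation marks a state that extends both ways in time, and edge
clamping keeps every annotated second usable, including the first and last
seconds of a video.

### Pathway fusion and channel attention

Both pathways are 3D convolutional stacks (`tiny`: a stem plus two stages of
two blocks, spatial stride 2 per stage, residual second blocks;
`resnet50-3d`: five stages with the conventional 4x width progression and
temporal kernels of 3 in the late slow stages). At each stage boundary a
lateral connection transforms the fast feature map with a time-strided
convolution (temporal kernel 5, stride 8 — the stride ratio of the two
pathways — output `2 * C_fast` channels) and concatenates it onto the slow
map's channels.

Squeeze-and-excitation attention operates on the slow pathway. The squeeze
is a global average over height, width, *and time*: the attended map is
4-dimensional, and including the temporal axis in the pool is the standard
extension of the (originally 2D) SE formulation to video features. The
excitation is a two-layer bottleneck `s = sigmoid(W2 %*% relu(W1 %*% z))`
with reduction ratio 16 (the customary SE default; the bottleneck keeps at
least one unit for narrow maps), and the gates rescale channels
elementwise. Placement is configurable and mirrors the ablation axes users
will want: `end` (after the last slow stage, before region pooling — the
default), `front` (after the stem), or `none`.

Because the squeezed descriptor is non-negative (it pools post-ReLU maps),
a zero-mean random `W1` can leave the narrow bottleneck entirely inactive
at initialization; `W1` is therefore initialized half-normal so attention
receives gradient from the first step.

### Box conditioning and the classifier

Recognition is conditioned on a detected box: the final fused slow map and
the final fast map are average-pooled over the box region (and over time),
concatenated, and passed through one hidden ReLU layer to five independent
sigmoid outputs. Independent sigmoids — not a softmax — because the task is
multi-label: Standing+Eating+(optionally Sleeping) is a legal target. The
region-pooling mechanism is a deliberate, simple choice; nothing in the
task requires anisotropic ROI-align resolution at desk scale, and the
pooling grid inherits whatever spatial resolution the backbone leaves.

Detection itself is pluggable. At desk scale an oracle detector perturbs
ground-truth boxes with Gaussian corner jitter, drops instances at a
configured rate, and adds uniform false positives — enough to exercise every
failure path (missed entities, unmatched detections) without training a
detector. Output from any real detector can be supplied as detection JSON.

### The loss family

For per-class positive counts `n_i` the class weights are

    w_i = (sum_j n_j) / (C * n_i),

which satisfies the two properties that define the weighting's purpose:
balanced counts give unit weights (so the weighted loss reduces exactly to
plain BCE), and rarer classes weigh more, scale-invariantly. The
class-weighted binary cross-entropy is applied per element on logits with a
numerically stable log-sigmoid (finite out to |logit| well beyond 50), and
focal modulation multiplies each element by `r * (1 - p_t)^r` before the
mean reduction. Three choices deserve explanation:

* **Elementwise modulation.** Modulating the already-reduced scalar loss is
  not well defined (there is no scalar `p_t`); the per-element reading is
  the only coherent one and is what the implementation uses.
* **The leading factor `r`.** The adopted focal form carries a leading
  factor `r` in addition to the conventional `(1 - p_t)^r`. A constant
  factor only rescales the effective learning rate, but it is kept by
  default for fidelity to the formulation this package implements;
  `orthodox = TRUE` drops it.
* **Exponent range.** A warning (not an error) is emitted for `r` outside
  `[2, 4]`, the range in which focal training behaves well in practice.

Weights may be computed from clip counts or frame counts — both give the
same ordering under a fixed per-video duration — and the weight function is
exposed so alternatives can be plugged in.

### Evaluation

Per-class AP is the area under the precision–recall curve built by a
descending-score greedy matching sweep at IoU ≥ 0.5, integrated with
all-point interpolation (the precision envelope made monotone from the
right) — the continuous-integral reading of mean average precision, not the
legacy 11-point approximation. Score ties are broken by input order, which
is documented because AP is tie-sensitive. mAP averages over classes with
ground-truth support. Because grid comparisons are sometimes read as
"accuracy" rather than AP, the evaluation also reports a thresholded
per-class accuracy (decision at score ≥ 0.5 on IoU-matched boxes, missed
ground truth counting against every positive label), labeled distinctly so
the two metrics cannot be conflated.

## The synthetic stall generator

The generator stands in for camera footage that cannot be shared. It
emulates the *structure* of a realistic observation campaign — not its
pixels:

* **Composition.** A default 32-video corpus is stratified to the seven
  legal combinations with video counts (3, 11, 4, 4, 3, 3, 4): Standing
  (with Eating the largest group, 11/32) dominates and the two recumbency
  postures are minorities — the class imbalance the weighted losses target.
  An i.i.d. sampling option exists; stratified is the default because the
  loss-comparison harness needs the imbalance reproduced exactly.
* **Geometry.** One animal per stall. The three postures are geometrically
  separable silhouettes: an upright tall body on legs (Standing), a
  chest-down compact mound (Sternal), and a flat, wide form with
  outstretched legs (Lateral). Eating lowers the head to ground level with
  a bobbing motion; a non-eating standing animal carries its head high.
* **Dynamics.** Awake animals sway slightly and show a gentle brightness
  flutter (≈2.5 Hz); sleeping animals are static. Sleeping is thus a purely
  temporal cue, visible only to the fast pathway — deliberately, so the
  dual-rate design is actually exercised rather than short-circuited by a
  static texture cue.
* **Nuisance.** Seeded background texture, slow global illumination drift
  (day/night variation), per-video animal color and position, and Gaussian
  pixel noise (default sd 2 gray levels).
* **Ground truth.** Boxes are computed from the rendered animal mask, so
  annotations are exact by construction; the mask is also exposed for
  testing the box invariant.

Defaults are desk-scale: 256 x 144 at 10 fps, preserving the 16:9 aspect of
1920 x 1080 / 30 fps source footage; full-scale rendering is a flag away.
What passing tests on this generator shows is that the pipeline's machinery
— sampling arithmetic, loss behavior under imbalance, attention plumbing,
detection matching, PR integration — is correct and that the recognizer can
learn separable spatio-temporal structure end to end. What it does not show
is robustness to the hard parts of real footage: occlusion, low-light
texture loss, animals at the frame boundary, or ambiguous sleeping
annotation; those remain properties of real data.

## Problem sizes and numerical choices

* The loss-comparison and end-to-end harnesses use 32 videos of 4 s each
  (128 annotated seconds, split 8:2), the `tiny` backbone at input size 32,
  8 epochs of Adam at step size 4e-3, batch 8 — sizes chosen so a full
  comparison cell trains in well under a minute on one CPU while keeping
  the stratified 32-video composition intact. Medians over 3 seeds are
  reported wherever a claim is directional (weighted ≥ unweighted minority
  recall; pipeline mAP ≥ 0.8).
* Convolution is im2col + BLAS with a cached gather index per input shape;
  the backward scatter exploits that each kernel-offset column maps output
  positions injectively into the input. Backpropagation through every layer
  (convolutions, laterals, SE, region pooling, head) is verified against
  central finite differences in the test suite.
* Degenerate inputs: constant (zero-range) images pass through CLAHE
  unchanged (a flat histogram is treated as a fixed point rather than
  letting tile equalization shift the constant); zero-strength jitter and
  zero-sd noise are exact identities; a zero class count is an error
  instructing the caller to merge or drop the class rather than silently
  producing an infinite weight.
* Every stochastic operation draws its seed from a named substream of one
  global seed (`derive_seed`), which is what makes corpora, splits,
  training, and the oracle detector bitwise reproducible end to end.
* Annotation coordinates are continuous and normalized; serialization
  rounds to 3 decimals (0.1% of frame size — below any pixel at the
  supported resolutions), and the pixel mapping happens only at clip
  assembly.

## Known limitations

* The hand-written network trains small models well but is not a
  general-purpose deep-learning stack: no GPU, no batch-level
  vectorization across clips, no pretrained weights. The `resnet50-3d`
  preset is structurally faithful and buildable but not practical to train
  here.
* One animal per stall; multi-entity scenes (and therefore entity
  association across detections) are out of scope.
* Video containers are not decoded; the supported source is a frame
  directory at a known rate, which is also the layout the generator writes.
* Sleeping is the hardest class by construction (purely temporal cue) and
  shows the lowest AP in the worked example; on real footage it is hard for
  annotation reasons as well, which no synthetic benchmark can capture.
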