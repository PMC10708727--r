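---
title: "Methods: virtual-sensor placement and multimodal HAR with harkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual-sensor placement and multimodal HAR with harkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harkit)
```

## The problem

Sensor-based human activity recognition (HAR) classifies fixed-length windows
of body-worn inertial measurement unit (IMU) data into activities. Two
practical questions dominate study design: *where on the body should the
sensors go*, and *how should heterogeneous modalities (IMUs and camera-based
2D pose) be combined*? harkit implements a complete desk-scale workflow
around both questions: a synthetic multimodal data generator, a vision-based
sensor-placement metric, pose/IMU fusion and windowing, evaluation protocols,
and small trainable window classifiers with last-layer personalization.

## The placement metric

Every 2D pose keypoint is treated as a *virtual sensor*: position traces are
causally linked to acceleration, so a keypoint whose trajectory distinguishes
activities marks a body location where a real accelerometer would be
informative. The pipeline has three phases.

**Phase 1 — preprocessing.** The 17 raw keypoints (nose, eyes, ears,
shoulders, elbows, wrists, hips, knees, ankles) are consolidated to 12 by
averaging the five head points into `head` and the two hips into `pelvis`.
Each series is then translated — once per series, preserving all
inter-keypoint geometry — so that the grand mean over valid keypoints and
frames is the image center (0.5, 0.5). Finally the series is restricted to
five candidate locations: the wrists, ankles and pelvis (the head carries
little movement information and is excluded by default).

**Phase 2 — the dissimilarity score.** For a keypoint subset $S$ and
activity $i$, the *activity vector* $A^S_i$ flattens the first $T$ frames
time-major, $(x_1, y_1, \dots, x_T, y_T)$ per keypoint, concatenating the
keypoint blocks. The placement score over $n$ activities is

$$D_S = \sum_{i<j}\left|1 - \frac{A^S_i \cdot A^S_j}
{\lVert A^S_i\rVert\,\lVert A^S_j\rVert}\right|,$$

the sum of absolute cosine distances over all $n(n-1)/2$ activity pairs.
Every pair term lies in $[0,2]$, hence $D_S \in [0, n(n-1)]$; the score is
invariant to positive rescaling of any vector and to activity order.
Multi-sensor subsets are scored on the concatenated vector, so combinations
are compared in exactly the same currency as single locations.

**Phase 3 — ranking.** All $2^5-1 = 31$ non-empty subsets are scored and
sorted by descending score; the best subset of each size is flagged. Ties
(scores equal within $10^{-12}$ — the resolution at which cosine round-off
is indistinguishable from equality) are broken toward fewer sensors, then
canonical candidate order, so degenerate inputs still rank deterministically.

**Cross-validation.** The score is cross-validated over contiguous temporal
blocks: each activity's trace is cut into `folds` (default 5) consecutive
blocks of `T_fold` frames, the score is computed per block index, and the
fold mean is reported. Contiguous blocks respect temporal autocorrelation;
shuffled folds would leak neighboring frames across folds. The corpus per
activity is capped at 3000 frames (5 min at 10 Hz) when available, and each
activity must supply at least 500 frames (50 s at 10 Hz) — shorter traces
are refused by name rather than scored unreliably. Whether centralization
should happen once per series or per fold is genuinely open; harkit
centralizes once per series, since the reference frame is a property of the
recording, not of a fold.

Degenerate inputs: an exactly-zero activity vector has no direction, so its
cosine is undefined; harkit raises an error rather than silently defining
`cos = 0`, which would corrupt rankings.

## The synthetic data generator

The generator emulates the structure of a realistic nursing-activity study:
10 subjects, 13 activities, five sensor locations, pose at 10 Hz with 17
keypoints and per-keypoint confidences, IMUs at 60 Hz with 14 channels each
(unit quaternion, quaternion-derived 4-channel angular velocity,
acceleration, magnetic field) — 70 IMU streams in total.

Keypoint motion is the simplest family whose per-activity spectral signature
the placement metric can detect: per keypoint and coordinate, a sinusoid
(frequency 0.4–2.5 Hz, amplitude 0.02–0.07 image units) plus a small linear
drift that resets at segment boundaries, plus i.i.d. Gaussian noise
(`noise_sd`, default 0.01 image units, on the order of a real pose
estimator's jitter). Subjects get a personal movement style — log-normal
multipliers on frequency and amplitude plus a small baseline shift
(`subject_sd`, default 0.15) — drawn deterministically from the subject
identifier, so the same subject moves consistently across recordings; this
is what makes leave-one-subject-out evaluation and personalization
experiments meaningful.

IMU channels are kinematically derived from the latent (noise-free) limb
trajectory whose image projection gives the keypoints, preserving the causal
position–acceleration link the placement metric relies on: acceleration is
the second-order finite difference of the latent 3D path scaled by an
assumed 1.7 m body height per image unit; the quaternion integrates a
smooth activity-dependent angular-rate process by small-angle steps and is
renormalized each sample; the 4-channel "angular velocity" is the per-sample
quaternion difference divided by the sample interval (the channel count
forces a 4-vector; the physical convention of the real sensor's quaternion-
derived rate is not published, so the derivative-of-quaternion reading is
the package's stand-in); the magnetic field is a slowly rotating unit
vector plus noise. Occlusion is emulated by `inject_gaps()`, which removes
whole blocks of pose frames at Poisson-placed gap starts.

What the generator does **not** emulate: camera-view foreshortening, pose
mis-detections (swapped limbs), correlated sensor noise, soft-tissue
artifacts, or gravity in the accelerometer channels. Passing tests therefore
show that the pipeline's logic is correct under its stated model, not that
the metric's rankings transfer to any particular real camera setup.

The planted-keypoint protocol is the generator's ground-truth instrument:
all activities share identical motion parameters at every keypoint except
one designated candidate location, where frequency and amplitude differ per
activity. The planted location is then the only one whose traces separate
the activities beyond noise, so the ranking must recover it — the package's
acceptance suite requires recovery in at least 19 of 20 replicates at
600 frames per activity and noise 0.01.

## Fusion and windowing

Pose (10 Hz) and IMU (60 Hz) streams are merged onto a regular master clock
at the IMU rate spanning the intersection of the IMU time spans. IMU
channels are taken by nearest neighbor (the sensors are assumed
time-synchronized, and quaternions do not admit naive linear interpolation);
pose features are linearly interpolated between bracketing frames. A pose
gap wider than `gap_max_s` (default 0.5 s, i.e. five missing frames at
10 Hz — enough to separate estimator jitter from genuine occlusion) yields
the sentinel value −1 in every pose column at the affected samples, as do
queries outside the pose range. Sentinels are confined to pose columns by
construction. The fused matrix has 14 columns per IMU plus 24 pose columns
(12 consolidated keypoints × 2 coordinates): 94 features for five sensors
with pose, 70 without.

Windows of `window_len` samples (default 600 = 10 s at 60 Hz) are cut from
the first sample at a fixed stride (default non-overlapping), a trailing
partial window is dropped, and each window takes the label with majority
occupancy of its time span; unlabeled windows are dropped. Modality
ablations (IMU-only, pose-only) are column masks over the same windows, so
ablated runs see identical segmentation.

## Classifiers and training

Three small architectures operate on `(window_len, features)` inputs, each
preceded by an input standardization stage that scales every feature column
by training-set statistics (sentinel −1 values pass through unmodified, as
in the imputation-then-train flow):

* **CNN-LSTM** — input, two convolutions, two LSTMs, dense softmax (six
  layers);
* **DeepConvLSTM** — input, four convolutions, two LSTMs, dense softmax
  (eight layers);
* **ResNet** — input plus repeated blocks of three convolutions, batch
  normalization and an activation. The published 11-layer accounting does
  not uniquely fix the repeat factor or skip topology; harkit uses two
  blocks (input + 2 × 5 named layers = 11) with an identity skip per block —
  a 1×1 projection when widths differ — followed by global average pooling
  and the dense softmax head.

Filter and recurrent widths are not part of the architectural contract and
default to 32/32, configurable down to desk scale (the test suite uses 4–8).
Training is mini-batch Adam (default learning rate 1e-4, the published
optimum for offline training) on categorical cross-entropy; the loss used in
training is the same implementation exposed as `cross_entropy()`. All
layers, including LSTM backpropagation through time and batch-norm batch
statistics, are implemented in base R with hand-derived gradients;
everything is deterministic under a seed in a single-threaded BLAS.

**Transfer learning.** `fine_tune()` freezes every layer except the final
dense head (frozen batch-norm runs in inference mode, so the backbone's
behavior is bitwise stable), splits the new subject's data 80:20 — by whole
recordings when at least a fifth recording exists, by windows otherwise —
and retrains the head for 10 epochs at batch size 7, returning evaluation
reports before and after on the held-out 20%. The head's learning rate
defaults to 1e-3 rather than the backbone's 1e-4: a linear softmax head on
frozen features is a convex problem that tolerates, and on ten epochs of a
small personal dataset needs, the larger step.

## Evaluation protocols

Three cross-validation schemes mirror the deployment questions: shuffled
k-fold over windows (optimistic — every subject is partially seen),
leave-recordings-out at an 80:20 window ratio with whole recordings never
split (the within-app regime; when honoring the ratio would leave no test
recording, the last recording stays on the test side and the shortfall is
logged), and leave-one-subject-out (the new-user regime). Reports carry
accuracy, macro-averaged F1 (the unweighted mean over classes present in
the truth — the conventional choice for imbalanced activity sets, and the
harshest on rare-class failure; the published F1's averaging mode is not
stated), and a row-normalized confusion matrix whose printed rendering
suppresses cells below 0.05. Per-fold metrics aggregate as mean ± sd.

## Problem sizes used in validation

The package's own experiments are sized for a single desk CPU, as stated
choices of the validation design: placement recovery uses 3 activities ×
600 frames × 20 replicates; the personalization experiment uses 4 subjects,
3 activities, 5 recordings per subject, 1-second windows (60 samples) over
one wrist IMU, 8-filter/8-unit CNN-LSTM backbones, 6 pretraining epochs,
and `subject_sd = 0.4` — a cohort with pronounced personal styles, the
regime personalization exists for. The production defaults (600-sample
windows, 32-wide layers, 13 activities) remain the package defaults; the
experiments demonstrate the mechanics, not production accuracy.

## Known limitations

* The motion model is stationary within a segment; activities distinguished
  only by long-range temporal structure (beyond sinusoid frequency and
  amplitude) are outside the generator's vocabulary.
* The placement metric compares truncated equal-length traces and is not
  alignment-invariant: a phase shift between otherwise identical activities
  registers as dissimilarity.
* The IMU simulator omits gravity and sensor biases; models trained on it
  will not transfer to real hardware.
* The hand-written neural engine is single-threaded dense algebra: adequate
  for desk-scale widths, two orders of magnitude from a production trainer.
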