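---
title: "Two-stage fall recognition from skeleton keypoints: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage fall recognition from skeleton keypoints: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posefall)
```

## The problem and the model

posefall classifies short windows of a 2D human-skeleton keypoint stream
(the OpenPose BODY_25 dialect: 25 keypoints per person in image pixel
coordinates with detection confidences) as *fall* or *activity of daily
living* (ADL). The difficulty is not separating falls from walking —
almost any posture feature does that — but separating them from
*confusing* ADLs: sitting down, squatting, bending over, whose early
kinematics resemble a fall's onset. The package treats a fall as a
state-transition process with time continuity, recognised in two stages.

**Per-frame posture features.** Only the main torso is used (neck,
mid-hip, hips, knees, ankles); arms and feet carry little weight
information and are dropped. From the segment vectors
(neck→mid-hip spine, hip→knee thighs, knee→ankle calves) we compute:

* five *deflection angles* — the angle in degrees between each segment
  vector and the vertical reference. In image coordinates (origin
  top-left, y downward) the reference is fixed as the up-image direction
  $(0, -1)$, so an upright torso scores ≈ 0° and a lying one ≈ 90°. The
  angle is the normalised dot product $\arccos(v \cdot g / |v||g|)$,
  cross-checked in the tests against an independent arctangent route to
  $10^{-9}$ degrees;
* the *spine ratio* — $|\text{spine}| / |\text{waist}|$, the projected
  neck-to-mid-hip length over the hip-to-hip width. A monocular camera
  cannot see a fall *toward* the lens in the deflection angle, but
  foreshortening collapses the projected spine while the waist width is
  preserved, so the ratio drops below 1 — the camera-facing route into
  the unstable states.

**Stage one: state division.** Two symbols integrate the features. The
*tendency symbol* is T1 when the spine angle is below the lower limit
(ALL = 30°) *and* the ratio is above the boundary (RB = 1.0); T3 when
the angle exceeds the upper limit (AUL = 50°) *or* the ratio falls below
RB; otherwise T2. The *steady symbol* evaluates four *pair* conditions
(spine+left thigh, spine+right thigh, left calf+left thigh, right
calf+right thigh), each requiring both angles below the angle limit
(AL = 30°); one true pair gives S1, none S2. The *human state* is then
STABLE for (S1, T1), DISORDER for (S2, T3), and FLUCTUATING otherwise,
scored 0/1/2. Two conventions worth stating because the source
formulations of these rules are ambiguous in print: (a) T1 requires the
ratio *above* RB and T3 fires when it drops *below* — the orientation
consistent with ADLs concentrating at high ratios and camera-facing
falls at low ones; (b) all comparisons are strict, so boundary equality
(angle exactly 30° or 50°, ratio exactly 1.0) falls to the middle or
unsteady level, making threshold sweeps deterministic. RB = 1.0 is the
default; values near 1.2 are defensible from the observed densities and
`stage_one_thresholds()` exposes it.

**Stage two: the time-continuous detector.** A *reference template*
$\xi = (P_x, P_y, H)$ stores the mid-hip position and torso length $H$
at the most recent STABLE frame. Three consecutive unstable frames open
a *non-stationary residence period* (NSRP); within it, three consecutive
STABLE frames abort with no event, and if ten frames elapse without an
abort the window is summarised by the feature vector $D = (\gamma,
\varepsilon, \tau)$ and classified once:

* $\gamma = \sum_i \mu_i$ with $\mu = \mathrm{softsign}(P_y - y_8)\,
  \lVert (P_x,P_y) - (x_8,y_8) \rVert_2 / H$ — the cumulative
  normalised centroid displacement, negative when the mid-hip moves
  down-image (toward the floor). $\mathrm{softsign}(x) = x/(1+|x|)$
  saturates at pixel scales, acting as a smooth direction term; a strict
  sign() is available behind `detector_config(soft_sign = FALSE)`.
  $\mu$ is recorded as 0 at STABLE frames;
* $\varepsilon = \sum_i \sum_{t} |y_{i,t} - \bar y_t| / H$ over the
  lower-limb keypoints $t \in \{10, 11, 13, 14\}$ (knees and ankles) —
  the vertical dispersion of the lower limbs, zero iff they are still;
* $\tau = \sum_i \mathrm{score}_i$ — the cumulative state score,
  bounded by twice the window length.

## Detector conventions where the procedure is underdetermined

Several details of the temporal loop admit more than one reading; the
package fixes them as follows (all are covered by the oracle-equivalence
tests, and the first is switchable):

* **Window placement.** The feature window is the ten frames *after*
  the three trigger frames; the trigger contributes to none of
  $\gamma$, $\varepsilon$, $\tau$. `detector_config(include_trigger =
  TRUE)` selects the trigger-inclusive variant.
* **Template freezing.** $\xi$ is refreshed only at STABLE frames
  outside an NSRP (or at the stable frame completing an abort). Inside
  an NSRP it is frozen, so $\mu$ always measures displacement from the
  last genuinely stable pose. $H$ in both $\mu$ and $\varepsilon$ is
  the template's frozen $H$, not the per-frame torso length: the
  template bundles $H$ precisely so that mid-fall foreshortening cannot
  rescale the features mid-window.
* **Abort priority.** If the same frame both completes a stable run and
  fills the window, the abort wins (no event).
* **Dropout policy.** Frames failing the validity rules (any required
  torso keypoint below `min_confidence` = 0.1, or waist width below
  `min_waist_px` = 1 px — the floor that protects the spine-ratio
  denominator) do not advance the state machine: the previous state is
  carried forward, and FLUCTUATING is assumed before the first valid
  frame (never silently stable). Inside a window such frames advance
  the frame count but contribute nothing to $\gamma$ or $\varepsilon$;
  coordinates are never fabricated.
* **Cold start.** If an NSRP opens before any STABLE frame has been
  seen, a provisional template is taken from the first valid frame of
  the NSRP — rare in practice, but it keeps the detector total.
* **After an event** (fall or not) counters reset and the template
  waits for the next STABLE frame; no alarm cool-down is modelled.

All window lengths are in frames. The defaults (3/3/10) correspond to
25 FPS footage; other frame rates need rescaled windows, which
`detector_config()` permits but the package does not automate.

## Classification

`fall_classifier()` trains one of six learners on $(\gamma, \varepsilon,
\tau)$: SVM with linear, polynomial $k(x,z) = (p\,x \cdot z + r)^u$ or
RBF $k(x,z) = \exp(-p\lVert x-z\rVert^2)$ kernels (p = 1/3 — one over
the number of features — r = 0, u = 3 by default), KNN (k = 5), a
decision tree split on information gain (the classic entropy-criterion
family; implemented through rpart with the information split, an
approximation to C4.5), and a random forest (100 trees). Cost,
neighbour count and tree count are conventional defaults exposed in
`classifier_config()`. Because the three features live on scales an
order of magnitude apart, SVM and KNN standardise features by default,
with the scaler fit on the training split only and bundled with the
model; trees are scale-equivariant and skip it.
`cross_validate()` runs seeded, label-stratified 3-fold
cross-validation. `confusion_metrics()` collapses a per-action event
count table with fall as the positive class; since precision and recall
depend on which class is "positive", it also reports the
non-fall-positive variants — the two conventions differ materially on
imbalanced tables and published figures do not always state which was
used. `roc_curve()` (via pROC, direction fixed so higher scores mean
more fall-like) uses trapezoid AUC.

## The synthetic motion generator

Real fall corpora are video datasets that cannot ship with a package;
`generate_sequence()` / `generate_corpus()` stand in with stick-figure
kinematics: fixed segment lengths, joint-angle trajectories, orthographic
projection, Gaussian keypoint jitter and confidence-zero dropout. The
defaults are chosen once from field conventions: torso 100 px and hip
width 40 px (resting spine ratio 2.5, typical of a standing adult at
moderate camera distance); thigh 0.55 and calf 0.50 of torso length;
jitter 1 px (pose-estimator noise at this scale); 40-frame sequences
(1.6 s at 25 FPS). Per-action contracts, before noise:

| action | spine | legs | mid-hip descent |
|---|---|---|---|
| WALK | < 12.5° (the postural-stability limit for upright sway) | thighs ±14°, calves ±8° | bobbing only |
| SIT_STAND | peak 40° (inside 30–50°) | thighs to 70° | 0.35 torso, recovers |
| SQUAT | ≤ 20° | thighs to 85° | 0.30 torso, recovers |
| BEND | 60–80° | < 15° | 0.08 torso |
| LATERAL_FALL | all five angles past 50° within a 10-frame ramp | with the body | 0.85 torso, stays down |
| FORWARD_FALL | < 30°; projected spine scales to 0.35 (ratio 2.5 → 0.875) | < 20° | 0.70 torso, stays down |

The camera-facing fall foreshortens the spine *first* (pitch toward the
lens), then drops the body: this ordering matters, because a descent
during still-stable frames would be absorbed into template refreshes and
erased from $\gamma$. Foreshortening itself is modelled by scaling the
projected spine segment only (hips fixed) — the minimal mechanism that
drives the spine ratio below 1.

What the generator deliberately does **not** model: perspective and
camera tilt, limb self-occlusion (dropout is independent per keypoint),
identity switches between people, soft-tissue and clothing artefacts in
keypoint placement, and the long-tailed confusion structure of real
pose-estimator failures. Passing tests on this corpus therefore
demonstrate that the pipeline's logic and arithmetic are correct and
that the features separate *kinematically idealised* falls from
confusing ADLs; they are not evidence about detection rates on real
video, where published results on the 191-video public Fall Detection
Dataset are the relevant benchmark.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 10⁴ random vectors for
the angle-oracle agreement (tolerance 10⁻⁹ degrees); 1,000 random
30–60-frame streams for the detector-vs-transcription equivalence
(exact to 10⁻¹²); 50 sequences per class for the feature-sign runs; and
a 100-sequence corpus (25 lateral falls, 25 camera-facing falls, 17
sit/stand, 17 squats, 16 bends, 1 px jitter) for the end-to-end
classifier recovery. Angle arithmetic clamps the cosine into [−1, 1]
before `acos` to absorb roundoff at the poles; the zero vector has no
deflection angle and is a domain error rather than a convention. Fold
assignment, corpus seeds and every classifier's RNG derive from a single
user seed; derived seeds stay below 2³¹ − 1.

## Known limitations

Single-subject tracking is greedy nearest-mid-hip only; long occlusions
can switch identities. The detector has no refractory period, so
prolonged thrashing yields one event per 13 frames. Thresholds are in
image-plane degrees and pixels: a strongly tilted camera violates the
vertical-reference assumption. The C4.5 stand-in differs from the
original in pruning details. Fall *direction* is not classified.
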