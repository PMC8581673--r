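---
title: "Hybrid detector + background-subtraction tracking: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid detector + background-subtraction tracking: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Classical centroid trackers for rodent behavior videos rely on background
subtraction: compare each frame against a reference image of the empty
arena, threshold the difference, and take the centroid of the foreground.
This fails as soon as anything else moves — the tether cable of a
head-mounted miniscope, an experimenter's hand — or when the animal barely
contrasts with the arena (a white mouse in a bright box). Conversely, a
learned object detector is robust to such clutter but only outputs a
bounding box, and the box center is a poor estimate of the animal's
position: the box reorients abruptly with posture changes even when the
animal barely moves.

`bhvtrack` combines the two so each covers the other's failure mode. Per
frame, in order:

1. **Mask** the frame to a user-defined tracking area; everything outside
   the polygon is overwritten with a background fill color, so off-arena
   structure can neither fire the detector nor appear as foreground.
2. **Detect** with a low confidence threshold (default `p >= 0.25`); a low
   threshold costs nothing because the next step arbitrates.
3. **Select** the box with the highest confidence `p`; ties go to the
   larger box, then to list order.
4. **Enlarge** the chosen box by 1.5x per side about its center (corners
   rounded outward, clamped to the frame) so it covers the whole animal
   even when the raw box is tight.
5. **Subtract** the background inside the enlarged box only, keep the
   largest 8-connected component, and report its pixel-mean **centroid** at
   sub-pixel precision.

If no detection survives, the frame is `undetected` (no coordinate is
invented); if the detector fired but no foreground pixel survives
thresholding, the point falls back to the enlarged-box center and is
flagged `fallback_box_center`. Both single-stage methods remain available
as first-class baselines (`track_config(method = "bg_only")` and
`"box_center"`), because the comparison against them is part of the
method's evidence and of this package's test suite.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `working_size` | 360 x 640 | px | all processing at a fixed cheap resolution; frames are bilinearly resized at ingestion |
| detect `threshold` | 0.25 | – | deliberately low; highest-p selection arbitrates among surviving boxes |
| `enlarge_factor` | 1.5 | – | per-side scaling of the chosen box so it covers the whole animal |
| median `k` | 25 | frames | temporal-median background: a pixel keeps the arena color unless the animal occupies it in half the sampled frames |
| threshold policy | Otsu | – | parameter-free, computed on the in-ROI luminance-difference histogram; a fixed 0–255 value is available for low-contrast scenes |
| `polarity` | `target_darker` | – | sign of the difference; switch for white animals on dark floors, `either` when unsure |
| opening kernel | 3 x 3 | px | removes sensor speckle and wire-thin structures before component labeling |
| `jump_px` | 40 | px/frame | feedback-loop "incorrect frame" flag at the working resolution |
| heat-map `bin_px` | 16 | px | about 24 bins across an open-field arena at 360 x 640 |
| `px_per_cm` | unset | px/cm | optional calibration; distances and speeds switch from px to cm units |

Background construction is unspecified territory: the temporal median over
`k = 25` uniformly spaced frames is the default because it is robust to a
moving animal, but a supplied empty-arena frame
(`estimate_background(method = "supplied")`) is always preferable when one
exists — on short clips where the animal lingers, the median inherits a
faint ghost of the animal and the centroid degrades by a pixel or two.

## The detector

The detection backend is pluggable (`bhv_detector`); three backends ship:

* **cnn** — a compact fully-convolutional network trained from random
  weights: five 3x3 convolutions (strides 2,2,2,2,1; channels
  3→8→16→32→32→128; leaky-ReLU 0.1) and a 3x3 linear head predicting, per
  16-px grid cell and anchor, `(tx, ty, tw, th, objectness, class scores)`.
  Anchors (2 by default) come from a seeded k-means over the training box
  sizes. A documented swap-in point for a pretrained backbone exists — the
  contribution here is the hybrid pipeline, not the backbone.
* **oracle** — replays ground truth with controllable corner jitter and
  miss rate, deterministic per (frame, seed); the tool for separating
  pipeline error from detector error.
* **blob** — wraps whole-frame background subtraction in the detector
  interface (also the `bg_only` baseline's engine).

Training follows the standard protocol for this task: mini-batch gradient
descent, 16 images per optimizer step, 20 epochs, learning rate 1e-4,
inputs letterboxed to a square (default 480 px). Within that fixed budget,
several design choices are the package's own, made once and documented
here:

* **Optimizer.** SGD with momentum 0.95. The adaptive alternative (Adam,
  also available) bounds per-parameter movement by roughly
  `learning_rate x steps`, which after 260 steps is an order of magnitude
  too little to separate objectness logits from random initialization;
  momentum SGD's gradient-proportional steps do not have that ceiling.
* **Loss.** YOLO-style sum (not batch mean) of: squared error on linear
  within-cell offsets and on sqrt box sides for the responsible anchor
  (weight 5), logistic objectness (weight 1; no-object cells 0.5), and a
  softmax class term (weight 1) when more than one class exists.
* **Box-target normalization.** Regression channels carry a fixed output
  gain of 0.1 (the usual "box std" normalization). Without it the
  squared-error terms sit two orders of magnitude above the objectness
  terms in curvature and oscillate at the shared learning rate instead of
  converging — the symptom is boxes whose height collapses while the loss
  still falls.
* **Initialization.** He-normal backbone; head biases start boxes at the
  cell center with the anchor's size and objectness at a low prior
  (logit −2), so early training is not swamped by the no-object term.
* **Stride 16, 3x3 head.** At stride 32 a grid cell is larger than a mouse
  at 224-px input; the residual within-cell offset error then dominates the
  IoU of small boxes. Halving the stride halves the pixel error at the
  same cell-fraction residual, and the 3x3 head kernel lets the offset
  regression see the feature neighborhood.
* **NMS at IoU 0.5** inside `detect()`, then thresholding, then descending
  sort — multiple boxes on one animal are collapsed before the tracker
  chooses.
* Determinism: all randomness runs through one seeded generator; training
  is documented as deterministic on a fixed BLAS only.

Detector quality is summarized as average precision at IoU 0.5 (AP@0.5),
computed by descending-confidence greedy matching with one-to-one truth
assignment and the interpolated precision envelope. AP@0.5 is adopted and
labeled as such wherever "precision" is reported.

## The synthetic scene generator

Every quantitative claim in the test suite runs on generated arenas with
exact ground truth. Targets are anti-aliased ellipses rendered by 4x4
supersampled coverage, so the analytic ellipse center *is* the true
centroid (the rendered intensity centroid agrees to < 0.3 px); the
annotation box is the tight bounding box of the rendered support. Three
regimes emulate the canonical noise conditions:

* **clean** — dark target, uniform light arena, per-pixel Gaussian noise
  (sd 2/255): the open-field situation.
* **wire** — a 3-px-wide tether cable of near-target intensity, drawn as a
  sagging quadratic curve from a top-edge anchor to the animal, bowing
  towards the animal's side of the arena and swinging as it moves. A
  quasi-static wire would be absorbed into the temporal-median background
  and defeat the point of the regime; tethered-recording cables are
  dragged around by the animal, and so is this one. Width 3 px is chosen
  to survive the 3x3 opening — as real cables do.
* **lowcontrast** — target/background luminance difference of 15/255 plus
  a lateral lighting gradient: the white-mouse-in-a-bright-box situation.

A **treadmill** variant confines the walk to a horizontal band, and a
**two_animal** variant renders two white-bodied targets with blue and
green center markers in separate half-arenas for identity-assignment
tests. Trajectories are bounded random walks (per-axis Gaussian steps,
reflecting walls).

What the generator does **not** emulate: fur texture and articulated
posture, shadows, specular reflections, lighting flicker, occlusions by
arena structure, and camera distortion. Passing tests therefore
demonstrate that the pipeline's logic is correct and that its ordering
claims (hybrid beats background-only under wire clutter; hybrid beats
box-center under box jitter) hold under controlled conditions — they do
not certify accuracy on any particular laboratory video, which still
depends on detector training data for that condition.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, origin top-left, x right / y down; a pixel's
  integer coordinate is its center. Boxes `(x, y, w, h)` are half-open.
  A 10x10 square at (50, 50) has centroid (54.5, 54.5).
* Polygon rasterization counts pixel centers inside or on the boundary;
  checked against a brute-force even-odd oracle.
* Enlarged-box corners round outward (floor/ceil) so coverage never
  shrinks; clamping to the frame happens last.
* Component labeling is 8-connected; equal-area ties break by the
  topmost, then leftmost bounding pixel.
* Empty masks raise an error from `centroid_of_mask()` — callers must use
  an explicit fallback, never a silent zero. An empty detection list gives
  status `undetected` with an absent centroid.
* Undetected frames are left absent by default; linear interpolation
  (`interpolate_gaps()`, gaps of at most 5 frames) exists but is off — the
  intended route is `collect_failures()`: export missed and implausible
  frames (status, confidence below `p_min`, or displacement above
  `jump_px`), relabel, merge via the annotation readers, retrain.
  Interpolated points are flagged like manual corrections since they are
  post-hoc edits, not tracker output.
* Frames are held as 8-bit arrays internally (quantization at ingestion),
  matching the 8-bit-per-channel contract and keeping thousand-frame
  videos in memory.
* Kinematics excludes steps across gaps rather than bridging them;
  bridging inflates distance across occlusions.

## Decisions where the design was genuinely open

* **Enlargement is side-wise** (each dimension x1.5), not area-wise; both
  readings are defensible and the side-wise one is adopted and tested.
* **Centroid from raw foreground pixels**, not the filled contour — the
  two agree for filled convex shapes, and raw pixels need no fill step.
* Tracking areas accept both rectangles and arbitrary simple polygons;
  how areas were drawn originally is unknowable, so both are supported.
* The feedback loop's "incorrect frame" rule is a displacement jump
  threshold (default 40 px/frame at 360 x 640); some such rule is needed
  and none is canonical.
* One optimizer update per mini-batch — the standard reading of
  "updated after several iterations".
* The `fill_color` of a tracking area defaults to black and is otherwise
  user-supplied; "the background color" is scene-dependent and no attempt
  is made to guess it.

## Problem sizes in the shipped tests

The test suite chooses sizes that exercise every claim while staying
desk-scale: 60–1000-frame synthetic videos at 180 x 320 or 360 x 640;
detector checks at 96-px input on 24–48 images for mechanics
(step counts, determinism, loss descent) and one full 200-train /
60-test run at 224-px input for held-out AP@0.5 >= 0.8; the 480-px
default input is exercised by a two-epoch instrumented run. The
acceptance script (`scripts/acceptance.R`) regenerates all of these from
scratch under a caller-supplied seed.

## Known limitations

* Single-animal identity only, unless animals carry distinct color
  markers; there is no cross-frame identity model (no Kalman filtering,
  no re-identification), and detector label switches are not reconciled.
* The from-scratch detector is appropriate for high-contrast laboratory
  scenes and for testing the pipeline; photorealistic videos warrant a
  pretrained backbone behind the same `bhv_detector` interface.
* The temporal-median background assumes a static camera and static
  arena; slow lighting drift or camera motion require a supplied or
  re-estimated background.
* Tracking is offline (whole sequences); there is no streaming mode.
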