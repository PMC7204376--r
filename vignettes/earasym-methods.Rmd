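---
title: "Quantifying facial-paralysis eye asymmetry with earasym: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying facial-paralysis eye asymmetry with earasym: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earasym)
```

## The clinical problem

Unilateral facial paralysis impairs voluntary movement on one side of the
face. Clinically it is graded with the Facial Nerve Grading Scale 2.0
(FNGS 2.0), which scores the brow, eye, nasolabial fold and oral regions
from 1 (normal) to 6 (no movement) by visual inspection — a procedure that
is slow and partly subjective. `earasym` implements an objective,
landmark-based measurement for the eye region: during an eye open–close
task, the two eyes of a healthy subject trace nearly identical aperture
trajectories, while in palsy the affected eye's trajectory is attenuated.
The magnitude of the disagreement between the two trajectories tracks the
clinical eye score.

The pipeline is: 68-point facial landmarks per frame → in-plane tilt
correction → amplified eye aspect ratio (EAR) per eye per frame → discrete
Fréchet distance between the two EAR curves (the *bilateral EAR
difference*) → nearest-class-median classification into an FNGS 2.0 eye
score.

## Amplified eye aspect ratio

Landmarks follow the 0-based iBUG 68-point convention (eye contours 36–41
and 42–47, nasal root 27, nose tip 33, brow reference points 19 and 24).
For the image-left eye in frame *t*:

$$
\mathrm{EAR}_{L,t} \;=\;
\frac{\lVert LM_{37}-LM_{41}\rVert + \lVert LM_{38}-LM_{40}\rVert}
     {2\,\lVert LM_{36}-LM_{39}\rVert}
\;\times\;
\frac{\lVert LM_{19}-LM_{33}\rVert}{\lVert LM_{27}-LM_{33}\rVert},
$$

and symmetrically (indices 42–47 and brow point 24) on the right. The
first factor is the classical eye aspect ratio: summed vertical eyelid
distances over twice the horizontal corner distance, near zero for a
closed eye. The second factor amplifies the bilateral contrast: brow
motion is also asymmetric in palsy, and the nasal root and tip barely move
during expression tasks, so brow-to-tip distance over nose length is a
stable, expression-sensitive multiplier. Because EAR is a ratio of
distances it is invariant to translation, rotation and uniform scaling of
the landmark set — verified end to end by a property test that applies
random global rotations and requires the final asymmetry statistic to
change by less than $10^{-6}$.

Tilt correction (rotation of each frame about the inter-eye midpoint $C$
so the eye-corner line is horizontal) is still performed by default: it
matters when landmark coordinates are exported alongside geometrically
normalized image crops, whose box is anchored at $C$ with half-width equal
to the interocular distance $d$, extending $0.5\,d$ above and $1.5\,d$
below. We take $d$ between the two eye-contour *centers* (not the outer
corners): the contour center is the common interocular convention for
error normalization and is stable under eye closure. EAR itself is
computed on tilt-corrected raw coordinates; no rescaling into the crop box
is needed since the ratio is scale-free.

## Bilateral asymmetry as a discrete Fréchet distance

The two per-frame EAR series $P$ (left) and $Q$ (right) are compared with
the discrete Fréchet distance of Eiter and Mannila: the minimum over all
monotone couplings of the two sequences of the maximum pointwise gap
$|p_i - q_j|$, computed by dynamic programming over the $|P|\times|Q|$
grid. Intuitively it is the shortest "dog leash" that lets both curves be
traversed in order. Unlike a per-frame maximum it tolerates small timing
offsets between the eyes (e.g. slightly asynchronous blinks) while still
penalizing amplitude differences, which is exactly the failure mode of
interest. A strict per-index variant (`coupling = "identity"`) is exposed
for sensitivity analysis. The implementation is validated against an
independent brute-force oracle (`frechet_naive`) that enumerates every
monotone coupling on short series; the two agree to $10^{-12}$ on 200
random pairs.

We deliberately do not assert the triangle inequality in tests: it does
not hold in general for min–max couplings. No temporal smoothing or
resampling is applied to EAR curves by default, because the measurement
model introduces none; an optional moving average can be layered on by the
caller.

## From asymmetry to an FNGS 2.0 eye score

`grade_from_total()` implements the scale's bookkeeping (region scores
plus a 0–3 secondary-movement score; totals map to grades I = 4, II = 5–9,
III = 10–14, IV = 15–19, V = 20–23, VI = 24). The eye-score classifier is
intentionally minimal: per-score class medians of the bilateral EAR
difference are computed on the training fold, and a new sample receives
the score with the nearest median (ties to the lower, i.e. milder, score).
This is the simplest model consistent with the well-separated per-score
intervals the asymmetry statistic produces; interval-threshold and 3-NN
variants are available behind `method =`. Pearson correlation is the
default association measure between the scalar feature and the ordinal
score (Spearman available). Cross-validation uses a seeded uniform
partition into *k* folds (sizes differing by at most one), unstratified by
default because nothing in the measurement model requires stratification;
a stratified variant is provided.

Detections that fail quality control are excluded before analysis.
With ground truth, a detection is incorrect when the eye-subset (indices
36–47) normalized mean error exceeds a threshold, default 0.08 — roughly
"the average eye-landmark error exceeds 8 % of the interocular distance",
a level at which lid distances are no longer meaningful. Without ground
truth, geometric sanity checks apply: a self-intersecting eye contour, an
eye taller than wide, or eye landmarks escaping the normalization box.
The pipeline runs these checks on the first (open-eye) frame, where the
contour is non-degenerate; at peak closure the lid contour legitimately
collapses to a line and such checks would be meaningless.
`apply_exclusions()` conserves counts exactly (per score, original =
retained + excluded), which is asserted as an invariant.

## The landmark detector

Detectors trained on normal-face databases fail on palsy faces —
asymmetric, incompletely closing eyes are out of their training
distribution — so the package includes a trainable cascaded
ensemble-of-regression-trees (ERT) detector. The cascade folds
$S^{t+1} = S^t + r_t(I, S^t)$: each stage $r_t$ is a gradient-boosted
ensemble of depth-$F$ regression trees over pixel-difference features,
fitted to the shape residuals (target − current) by least squares with
shrinkage $\nu$ (the cascade's regularization parameter; the supported
tuning grid spans depths 2–10 and shrinkages 0.001–0.9). Feature pixels
are shape-indexed: stored as (nearest mean-shape landmark, offset) and
warped to each sample's current shape through a similarity transform, so
features track the face through pose changes. Leaf values are
$\nu$-scaled mean residuals, so the training residual sum of squares is
non-increasing tree by tree; the recorded training-NME trace is asserted
to be non-increasing in the acceptance suite.

Design choices worth naming:

* **Residual frame.** Residuals are fitted in image coordinates rather
  than the mean-shape-normalized frame of the original ERT formulation.
  The rendered training faces share a canvas scale, so the extra
  normalization machinery would add complexity without measurable benefit
  at this scale; the shape-indexed feature warp still provides pose
  invariance where it matters (feature extraction).
* **Accuracy metric.** The normalized mean error (NME) is the mean
  per-point Euclidean distance divided by the truth's interocular
  distance — the standard definition; a squared-norm variant exists
  behind `squared = TRUE` but is not scale-normalized and is excluded
  from all defaults.
* **Initialization.** Training samples start from another training
  image's shape (or the mean shape) aligned into the face box — the
  ground-truth landmark bounding box padded 20 % during training, a
  caller-supplied box at inference. Face *detection* is out of scope.
* **Degenerate tree nodes.** A node with fewer than two samples, or where
  no sampled split separates its samples, becomes a pass-through (all
  samples left, threshold $+\infty$); empty leaves contribute a zero
  update. Ties in candidate-split scores keep the first candidate.
* **Serialization.** Models round-trip through a versioned JSON file at
  17 significant digits, which reproduces IEEE doubles exactly; a
  reloaded model predicts bit-identically, and the test suite asserts it.

Model training is deterministic given its seed: the feature pools,
candidate splits and initial shapes all derive from one RNG stream, and
all seeded helpers in the package save and restore the caller's RNG
state.

## The synthetic patient generator

The clinical images behind this method cannot be redistributed, so the
package ships a generator that emulates the *structure* of such data and
defines the package's study conditions.

A fixed, exactly mirror-symmetric 68-point template face (midline through
nasal root and nose tip) performs one smooth eye-closure cycle over
`n_frames = 30` frames (one second at the 30 frames/s the pipeline
targets): the four lid points of each eye are displaced vertically by
$A\,(1-\cos(2\pi t/n))/2$, with $A$ the open-eye lid gap times
`closure_amplitude` (default 1, complete closure); eye corners stay
fixed, which keeps the EAR denominator stable, mirroring real eye-closure
kinematics. The affected side executes the same trajectory scaled by a
grade-dependent *residual fraction*, defaulting to
1.00, 0.80, 0.55, 0.30, 0.10, 0.00 for scores 1–6 — a discretization of
the scale's verbal bands ("slight weakness > 75 % of normal" … "trace
movement", "no movement"). Grade 1 is therefore exactly symmetric and
grade 6 keeps the affected eye immobile. Each frame then receives an
in-plane head rotation drawn uniformly within ±3° (patients sway while
performing tasks; tilt correction must undo this) and Gaussian landmark
jitter of 0.3 px standard deviation emulating detector noise. Both values
are fixed defaults chosen once as plausible magnitudes for seated
patients filmed at desk distance; they are configurable but are not
tuned per experiment.

What the generator does *not* emulate — and hence what passing tests do
not show about clinical data: appearance variation (illumination, skin
texture, occlusion), 3-D pose, synkinesis and other secondary movements,
blink-timing pathology, and real detector error structure (jitter here is
i.i.d. Gaussian; real errors are spatially correlated). Results on the
synthetic cohort demonstrate internal consistency of the method, not
clinical accuracy.

For detector training, faces are rendered procedurally from the template:
seeded shape variation (independent per-eye openness, mouth opening, brow
raise), a random similarity pose inside the canvas, then flat-shaded
polygons (skin ≈ 205, brows 70, eyes 45, mouth 95 gray levels) over a
background gradient with Gaussian pixel noise — contrasts chosen so
pixel-difference features are informative, with no attempt at
photorealism.

## Problem sizes and reproducibility

The package's own experiments, exercised by the test suite and by
`scripts/acceptance.R`, use: a cohort of 15 synthetic patients per score
(90 total, 30 frames each) for the median/correlation/cross-validation
analyses; and 60 rendered faces at 96 px (80/20 train/test split, two
initializations per face, 6 stages × 60 trees of depth 5, shrinkage 0.1,
150-pixel feature pools) for the detector experiment. These sizes were
chosen so the full analysis reruns in well under a minute on one CPU
while leaving each result comfortably clear of its pass/fail boundary.
Every stochastic step takes an explicit seed, and repeated runs are
asserted to be identical down to the serialized bytes where that is the
contract (cohort regeneration, model serialization, report content).

## Known limitations

* Only in-plane rotation is corrected; out-of-plane head pose will bias
  EAR through foreshortening.
* The amplification factor assumes the brow reference points and nose
  landmarks are reliably detected; gross brow mis-detection propagates
  into both eyes' EAR.
* The classifier is one-dimensional by design; it cannot express
  disagreement between asymmetry and score that a multi-feature model
  might capture.
* The detector is desk-scale: it demonstrates the training algorithm and
  its invariants on rendered faces, and is not a substitute for a model
  trained on annotated clinical images.
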