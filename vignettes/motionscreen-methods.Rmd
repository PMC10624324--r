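---
title: "Methods: screening functional-test execution from 2D pose keypoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening functional-test execution from 2D pose keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionscreen)
```

## The problem

Clinical functional tests such as the Single Leg Squat Test (SLST) and the
Step Down Test (SDT) are scored by physiotherapists watching the patient and
ticking off execution errors — loss of balance, excessive arm movement,
forward trunk lean, insufficient squat depth, pelvic drop, tremor. The
assessment is binary per error and inherently subjective. `motionscreen`
implements a camera-based alternative: a single frontal-plane RGB recording
is run through a markerless pose estimator (OpenPose's BODY_25 model, 25
landmarks per frame with confidences), kinematic signals are derived from
the landmark time series, each signal is reduced to its range of movement
(ROM), and a boosted decision-tree classifier is trained against the
experts' own consensus ratings. The package also ships a full synthetic
cohort generator, so every stage can be validated end to end without any
recorded video.

## Kinematic signals

Three families of per-frame signals are computed from the keypoint series,
using the pixel coordinates of the image (origin top-left, y downward):

* **Joint angle** — the interior angle at vertex $B$ of three keypoints,
  $\angle ABC = \arccos\left(\frac{\vec{BA}\cdot\vec{BC}}{|\vec{BA}||\vec{BC}|}\right)$,
  in $[0, 180]$ degrees. The cosine is clamped to $[-1, 1]$ before the
  arccos so collinear configurations cannot produce NaN through floating
  point.
* **Keypoint-pair orientation** — the angle of the vector $\vec{AB}$
  against the image horizontal. We use the quadrant-aware arctangent
  (`atan2`) rather than the plain ratio arctangent: the plain form cannot
  distinguish a leftward from a rightward lean, while its magnitude agrees
  wherever both are defined. The y coordinate is negated first, so that
  "up on screen" is positive and a vertical pair measures +90°.
* **Relative distance** — the Euclidean distance $|AB|$ divided by the same
  frame's trunk length $|K_1 K_8|$ (neck to mid-hip). The per-frame
  normalizer removes body-height and camera-distance scale; a sequence-level
  normalizer would additionally suppress genuine trunk-length foreshortening
  and is not what the ratio definition states.

The default catalogue holds 15 signal definitions — three pair
orientations, seven joint angles, five relative distances. Its index tuples
are kept exactly as published for the reference cohort even where a row's
name and the BODY_25 anatomy of its indices disagree (e.g. "RWristMidHip"
uses indices (4, 7), which are the two wrists); the intended anatomy cannot
be reconstructed from the source, so the printed tuples are treated as the
definition and a YAML override (`read_catalogue_yaml()`) is provided for
corrected catalogues.

Frames in which any contributing keypoint is missing are masked out of the
signal rather than interpolated at signal level; gap repair happens once,
at pose level (`fill_missing()`, linear interpolation across gaps of at
most 5 frames ≈ 167 ms at 30 fps — long enough to bridge detector dropouts,
short enough not to fabricate motion).

## Features and labels

Each recording is reduced to one feature vector: the ROM (max − min over
valid frames) of each catalogue signal, 15 features by default. An
`extended` mode adds min, max, median and mean per signal (75 columns) for
exploratory use. One vector per recording — not per repetition — matches
the one-label-per-subject-per-test structure of expert assessment; no
repetition segmentation is attempted. Features are not standardized:
decision trees are scale-invariant.

Expert labels enter as subjects × raters × parameters binary tables.
Per parameter, Fleiss's kappa
$\kappa = (\bar{P} - \bar{P_e})/(1 - \bar{P_e})$ quantifies chance-corrected
panel agreement; when every rating in a table is identical the formula is
0/0 and the complete-agreement convention returns 1 (this case occurs in
real screening data whenever an error is never observed). Consensus labels
are majority votes. A parameter is **eligible** for classification when
$\kappa \ge 0.41$ (the conventional floor of moderate agreement, inclusive)
and the smaller consensus group has at least 8 subjects. The minority floor
of 8 is the smallest integer that reproduces the published eligible sets
(five SDT parameters, two SLST parameters) from the packaged reference
agreement table; both thresholds are configurable.

## The classifier

`train_adaboost()` implements two-class discrete AdaBoost (SAMME) over
depth-bounded trees grown by weighted Gini impurity:

1. sample weights start at $1/n$;
2. round $t$ draws $\lfloor\sqrt{d}\rfloor$ candidate features (schedule
   keyed to `(seed, round)`, so reshuffling the training rows does not
   change the model), and fits a tree of depth ≤ 3;
3. the weighted error $\varepsilon_t$ gives the learner weight
   $\alpha_t = \eta \cdot \ln\frac{1-\varepsilon_t}{\varepsilon_t}$ with
   learning rate $\eta = 0.1$;
4. misclassified sample weights are multiplied by $e^{\alpha_t}$ and
   renormalized;
5. prediction is the sign of $\sum_t \alpha_t (2 h_t(x) - 1)$, ties going
   to class 0 (non-faulty). The positive class is always "error present",
   so sensitivity is error detection and specificity is recognition of
   correct execution.

Defaults (50 learners, $\eta = 0.1$, depth 3, $\sqrt{d}$ feature subsets,
random state 42, 80/15/5 stratified split) follow the reference study
configuration. Degenerate rounds are defined deterministically: a perfect
round ($\varepsilon_t = 0$) keeps the learner with a large capped weight
and stops; a failing round ($\varepsilon_t \ge 0.5$) redraws its feature
subset once and stops after the retry, so $\alpha_t$ can never go negative.

Split selection follows a documented determinism contract — candidate
thresholds are midpoints between consecutive distinct sorted values,
impurities are compared at a resolution of $10^{-9}$, ties break toward
the lower feature index and then the lower threshold, and leaf ties go to
class 0. The contract exists so that an independently coded exhaustive
enumeration (used as a test oracle) reproduces the ensemble label for
label; without a fixed tie rule, floating-point noise would make "equally
good" splits implementation-defined.

The 80/15/5 partition uses largest-remainder rounding on the total sizes
first, then per class, repairing the class allocation to the total targets;
remainder ties prefer the earlier split. On a 46-subject cohort this yields
37/7/2 — and a 2-subject test split is statistically meaningless, which is
why cohort-scale evaluation uses stratified 5-fold cross-validation
(`cross_validate_adaboost()`) instead; the plain split is retained for
large-sample use and for reporting.

## The synthetic cohort generator

`generate_dataset()` emulates the reference protocol: 46 subjects by
default, clips of 15 s at 30 fps in a 1280 × 720 image, three squat
repetitions per clip, three simulated raters. It is a *signal-level*
simulation, not a biomechanical model: only the kinematic signatures the
catalogue monitors are modeled.

* **Anthropometry.** Trunk length is drawn at 170 px with the cohort's
  body-height coefficient of variation (9.9/173.8), clamped to ±2 SD so the
  tallest subjects stay inside the frame; limb segments are fixed
  proportions of the trunk.
* **Base motion.** The stance knee angle sweeps 175° → depth → 175° per
  repetition under a raised-cosine envelope; the squat depth defaults to
  100° with a per-subject offset (SD 5°). The knee angle is imposed
  exactly by a symmetric two-link construction (shank and thigh tilt by
  opposite half-angles, hip over ankle), so the generated knee signal is
  analytic ground truth for the kinematics layer. The pelvis, trunk, head,
  arms and free leg ride rigidly on the stance hip; the stance foot stays
  planted; the SDT raises the stance foot by a 20 cm step (0.42 trunk
  lengths) and lowers the free foot toward the floor. Gaussian jitter
  (default 1 px) stands in for detector noise; an optional dropout rate
  produces missing keypoints for testing the cleaning stage.
* **Natural variation** (on by default, `natural_variation = FALSE` for
  geometric ideals): per-subject trunk sway up to 2°, hip tilt up to 1.5°,
  arm drift up to 6 px — within what raters would accept as correct. This
  is what makes the zero-effect classification problem genuinely
  unlearnable rather than trivially constant.
* **Error injection** (`inject_error()`): each mode perturbs the keypoints
  an expert would watch, monotonically in its magnitude, with magnitude 0
  an exact identity. Magnitudes are expressed in the units of the signal
  they perturb. Defaults, chosen once as clearly visible expert-level
  effects at the study's camera geometry (≈ 3 mm/px): forward lean 15°,
  hip drop 12°, shallow squat 40° of missed depth, arm deviation 120 px,
  balance sway 60 px, tremor 4 px at 8–12 Hz (physiological tremor band,
  below the 15 Hz Nyquist limit of 30 fps capture; independent phases per
  keypoint and coordinate so joints genuinely deform). Balance sway moves
  everything above the ankles — a whole-skeleton translation would be
  invisible to all three signal families, which are translation-invariant
  by construction.
* **Raters.** Each simulated rater reports the true label, flipping
  positives with probability 1 − sensitivity and negatives with
  1 − specificity (defaults 0.9/0.95; perfect raters reproduce truth and
  give κ = 1).
* **Limb assignment.** By default stance limbs alternate across subjects,
  as in a study recording both sides. Because the signal catalogue is
  side-specific, a mixed-limb cohort splits each error's signature across
  left- and right-side features; validation cohorts therefore use
  single-limb generation (`limbs = "right"`), where each error mode
  shifts its target features by several pooled standard deviations at the
  default magnitudes.

## Validation problem sizes

The test suite validates the kinematics against independent trigonometric
oracles on 1,000 random configurations (tolerance 1e-9 degrees), Fleiss's
kappa against a pairwise-counting oracle on all 4,096 binary tables of 4
subjects × 3 raters (tolerance 1e-10), and the boosting loop label-for-label
against an exhaustive-stump reference on ~200 small two-feature datasets.
End-to-end parameter recovery runs one 200-subject single-limb cohort per
error mode (balanced prevalence, perfect raters, 5-fold cross-validation)
and requires sensitivity and specificity ≥ 0.9 per mode, plus a zero-effect
cohort whose accuracy must stay within ±0.1 of the majority rate. These
sizes keep the whole suite under a few minutes on one CPU while leaving the
Monte-Carlo error of each check well below its acceptance margin.

## Degenerate inputs and numerical choices

* Keypoints with confidence < 0.1 **or** coordinates exactly (0, 0) are
  missing (OpenPose emits `(0, 0, 0)` for undetected joints).
* Zero-length limb vectors and coincident orientation pairs raise classed
  degenerate-geometry errors at the primitive level; at signal level such
  frames are masked invalid instead.
* Trunk lengths ≤ 1 px invalidate the relative-distance normalizer for the
  frame.
* Multi-person frames keep the person with the highest mean keypoint
  confidence (deterministic; first wins ties).
* All randomness flows from explicit seeds through a 32-bit-safe derivation
  function; RNG state of the calling session is saved and restored around
  every internal draw.
* Pose and model serialization writes doubles with 17 significant digits,
  the shortest representation that round-trips IEEE doubles exactly; this
  is what makes feature tables rebuilt from serialized sequences
  bit-identical.

## Known limitations

* The simulation is kinematic, not dynamic: no momentum, no ground-reaction
  constraints beyond a rigid floor, no detector-specific error structure
  beyond Gaussian jitter and optional dropout. Passing the recovery suite
  shows the pipeline recovers *injected* signatures; it does not establish
  clinical performance on real recordings.
* The catalogue's printed index tuples are used as-is, including the
  anatomically inconsistent rows; results on real data would inherit that
  inconsistency unless an overridden catalogue is supplied.
* Only frontal-plane 2D geometry is represented; out-of-plane rotations
  (e.g. true forward lean toward the camera) are modeled by their in-plane
  signature only.
* Binary ratings, three raters, two categories: no weighted kappa, no
  ordinal scales.
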