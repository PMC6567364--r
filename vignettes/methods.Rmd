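---
title: "Statistical functionals and subject-independent emotion classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical functionals and subject-independent emotion classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emofun)
```

## Overview

`emofun` analyses multimodal recordings of participants watching
emotion-elicitation film clips. One participant watching one clip is a
*segment*; its ground-truth label is the clip's target emotion, and it
enters the analysis only if the participant self-rated that emotion above
zero on a 0–10 scale. Four sensor modalities are summarised into a fixed
727-entry feature vector per segment, features are screened by one-way
ANOVA, and a one-vs-one RBF SVM is evaluated under leave-one-subject-out
cross-validation. Because the original multi-sensor recordings of such
studies are rarely deposited, the package ships a first-class synthetic
cohort generator whose draws have configurable emotion-conditional
structure; all tests and the acceptance analyses run against it.

## The functional layer

Every extractor is built from four primitives (`derivative()`,
`basic_stats()`, `threshold_runs()`, `duration_stats()`).

**Derivatives.** Velocity is the per-frame first difference and
acceleration the difference of the velocity, both in value-per-frame
units. We deliberately do not divide by the frame interval: extraction is
framewise, and only *durations* are converted to seconds through the
sampling rate (30 frames/s for camera streams, 32 Hz for the wrist
sensor). The first `order` entries of a derivative are missing, and a
missing input frame propagates to every difference involving it.

**Basic statistics.** Mean, range, minimum, maximum, standard deviation
and variance over non-missing frames. The sample (n − 1) variance
convention is used throughout; a single-frame channel has zero spread by
definition. An all-missing channel propagates `NA` — statistics are never
silently zero-filled.

**Threshold runs.** The event device underlying all duration features: a
run is a maximal stretch of consecutive frames strictly beyond the
segment's own mean ± SD of the channel in question. Design choices worth
stating:

* *Strict inequality with ties outside runs.* This makes the
  zero-variance case degenerate-safe: on a constant channel no frame is
  strictly beyond its own mean, so the run set is empty rather than
  covering everything.
* *Missing frames break runs* and are excluded from the mean/SD.
* *Magnitude floors.* Fast/slow changes are detected on |velocity| and
  continuous/steady on |acceleration|. For these non-negative magnitude
  channels the below-threshold rule uses `max(mean − SD, 0)`; without the
  floor a high-variability channel would have a negative threshold and
  the symmetric rule would select nothing by construction.
* *Affine equivariance.* Mean ± SD thresholds commute with positive
  affine maps, so per-segment min–max (light) normalisation of a channel
  before extraction leaves every run-derived feature unchanged. This is
  asserted as a property test.

The mean ± SD rule is the established event-detection device for tonic
autonomic signals; extending the same rule to all modalities (AU
activity, gaze change, pupil size, head movement) is a uniformity
decision of this package, flagged as such rather than presented as an
external fact.

**Duration statistics.** Per run set: max, min, range and mean duration
in seconds, rate of run frames to total frames (always in [0, 1]), and
run count. An empty run set yields all zeros. The head-pose event block
uses a seven-value variant (adding duration variance and total duration)
to match that modality's richer inventory.

## The four extractors

* **Facial (288).** Six AU intensity channels in [−1, 1] plus velocities
  and accelerations (18 low-level channels): 6 statistics × 18 = 108,
  plus 6 duration statistics × 5 run types (AU-active, fast, slow,
  continuous, steady) × 6 AUs = 180. AU-active runs threshold the raw
  intensity above its segment mean + SD, consistent with the global
  device.
* **Head (184).** Yaw/pitch/roll with derivatives (9 channels): 54 basic
  statistics; 24 direction-duration statistics over six directions
  (left/right from yaw, up/down from pitch, clockwise/anticlockwise from
  roll), each with a configurable dead zone of 5° around frontal (there
  is no single standard angular threshold; 5° is a conventional
  frontal-pose tolerance and is config-exposed); 12 duration-rate and
  direction-diversity rates; 6 change-in-direction rates; 4
  direction-change counts; 84 event-block values (7 statistics × 4 event
  types × 3 axes). The *diversity rate* (distinct directions visited
  during non-frontal frames, divided by 6) and the *change rate*
  (transitions landing in the direction, per total frames) are
  reconstructions: the inventory names these features without defining
  them, and any deterministic, documented reading is acceptable for the
  pipeline's purposes.
* **Eye (147).** Per-eye gaze-point displacement with derivatives, the
  left-minus-right eye-to-tracker distance difference (an approximate
  head-rotation cue), and per-eye pupil size normalised by its segment
  mean (pupil normalisation has no single standard; division by the
  segment mean is the simplest scale-free choice): 54 basic
  statistics; 9 absence statistics (mean/SD/variance of the left-only,
  right-only and both-pupil absence indicators); 24 fast/slow gaze-change
  duration statistics; 18 head-rotation duration statistics (left
  rotation, right rotation, either — detected when the distance
  difference crosses its segment mean ± SD); 24 large/small pupil
  duration statistics; 18 absence-run duration statistics. Frames with
  undetected eyes are missing, never zero-filled, and absence episodes
  are first-class events rather than artifacts to be repaired.
* **Autonomic (108).** SCL and temperature with derivatives (6 channels):
  36 basic statistics plus 6 duration statistics × 6 run types (high,
  low, fast, slow, continuous, steady) × 2 signals = 72.

Block lengths 288 + 184 + 147 + 108 = 727 and the name↔position bijection
are asserted when the registry is first built. Absent modalities produce
missing-valued blocks of the correct length, and the classifier for a
modality uses only segments where that modality is present.

## Selection and classification

**ANOVA selection.** The classical equal-variance one-way F test is
applied per feature with the six emotions as groups; features with
p ≤ α (default 0.05) are kept. The implementation is vectorised over
features (selection runs inside every cross-validation fold, so per-fold
cost matters) and is cross-checked against `stats::oneway.test()` in the
test suite. Zero-variance features have an undefined F and are never
selected. With a stimulus-language stratum, a feature must be significant
in *both* languages — the common-feature intersection that makes the two
stimulus sets comparable. The intersection can be applied inside each
training fold or once globally; per-fold is the leakage-safe default and
the global variant is off by default.

**Normalisation.** Per-feature min–max to [0, 1], fitted on the training
fold and applied unchanged to the test fold (test values may fall outside
[0, 1]); constant training features map to 0.

**SVM.** One binary libSVM C-classifier (RBF kernel) per unordered class
pair — 15 machines for six classes — with majority-vote decoding. Ties
are broken by the summed signed pairwise decision values in each class's
favour, then by the lowest class index; the decoder must be
deterministic, and this order is the least arbitrary one available. Hyper-parameters come
from a powers-of-two grid (cost 2⁻⁵…2¹⁵, γ 2⁻¹⁵…2³ by default) chosen by
an inner stratified cross-validation on the training fold only. The inner
folds are assigned deterministically (round-robin within class, no RNG)
so that identical inputs give identical reports. Tuning could also use
training accuracy directly; an inner CV is the choice least prone to
overfitting the cost parameter.

**Cross-validation.** The leave-one-out unit is the *participant*: all of
a subject's segments are held out together, which is the only reading
consistent with a subject-independent evaluation. Segment-level folds are
available behind a flag for comparison. Selection and scaling are
re-fitted inside every fold; the recorded per-fold selection masks make
the no-leakage property directly assertable by recomputation, and the
test suite does exactly that. Folds whose training part loses a class are
skipped with a warning and recorded.

## The synthetic cohort generator

The generator emulates the study design: `n_participants` (default 29)
each watch the twelve default clips (six emotions × English/Arabic, with
the study's stimulus durations of 30–234 s), yielding one multimodal
segment and one self-rating per participant × clip.

* **Class effects** are additive mean shifts per channel:
  `effect_size[modality] × channel SD × pattern`, where the pattern is a
  centred six-value sequence with unit population SD, rotated by one
  position per channel so the six classes are jointly separable even
  where a pair coincides on a single channel. An optional per-modality
  variance scaling makes classes heteroscedastic. Real per-emotion
  physiological effect magnitudes are essentially unknown; the
  defaults are free
  parameters of the generator, chosen once (moderate effect 1, noise
  multiplier 1) as a plausible middle ground.
* **Subject structure**: each participant draws a per-channel baseline
  offset (SD = `subject_sd` × channel SD, default 0.5), shared across all
  their segments. This is what makes subject-level cross-validation
  meaningfully harder than segment-level.
* **Eye absence** is injected as validity-flag-false episodes (per-frame
  start probability, geometric lengths); pupil and gaze values during
  absence are missing, never zero-filled.
* **Self-ratings**: the target emotion is felt with probability
  `felt_probability` (default 0.85); felt ratings are a truncated
  discrete draw on 1–10 peaked at the clip's configured intensity, and
  non-target emotions get independent low-intensity draws.
* **Survey analogue**: respondents watch clips in the fixed viewing order
  (per emotion, English then Arabic) and drop out after each clip; the
  default dropout profile is derived from the emulated study's per-clip
  respondent counts (345 down to 166), and acceptance is Bernoulli per
  clip with probabilities emulating the reported acceptance pattern.

What the generator does *not* model — tonic/phasic electrodermal
decomposition, facial-muscle kinematics, autocorrelated gaze scanpaths,
rating anchoring — bounds what passing tests mean: they demonstrate that
the pipeline's statistical machinery is correct and leakage-free under
the assumed class-conditional structure, not that real recordings would
reach any particular accuracy.

## Calibration and recovery experiments

Two subtleties surfaced while designing the acceptance analyses; both are
properties of the study design, not of the implementation.

* **Type-I calibration needs iid segments.** With subject baseline
  offsets, the emotion groups of a one-way ANOVA are blocked by
  participant (everyone contributes one segment per emotion per
  language), which makes the naive F test conservative. The calibration
  experiment therefore sets `subject_sd = 0`, the null under which the F
  test is exact; the selection rate is averaged over five independent
  cohorts because the 727 functionals of one cohort are strongly
  dependent, and the Monte-Carlo SE is taken from the replicate spread.
* **Recovery needs equal-duration clips.** With one clip per emotion,
  emotion-specific clip durations are themselves a deterministic class
  effect in *every* modality (counts and total-duration functionals scale
  with segment length). The recovery experiment — autonomic-only effects
  of 3 within-class SDs, 16 participants × 6 English clips of 30 s — uses
  equal durations so that the null modalities genuinely carry no class
  signal; their accuracies are then judged against chance with binomial
  noise at the *subject-fold* level (n = 16), since a held-out subject's
  six segments share one baseline offset and per-segment correctness is
  clustered.

## Problem sizes and numerical choices

The shipped experiments are sized for a single CPU: the demonstration
pipeline uses 30 participants × 12 clips of 20 s with a coarse 3 × 3
hyper-parameter grid; the recovery experiment uses the 4 × 4 grid
spanning the default ranges; null-calibration cohorts use 6 s clips. All
seeds are explicit, every stochastic stage derives from a single
configured seed, and two runs with the same configuration produce
byte-identical artifacts (asserted via per-file checksums recorded in a
sidecar `metadata.json` together with the configuration hash and seed).

Tolerances: variance/SD pairs agree to 1e−10 relative; the vectorised F
matches `oneway.test` to 1e−10; Welch statistics match the closed form to
1e−12. Degenerate inputs are handled explicitly rather than defensively:
zero-variance channels give empty run sets, all-missing channels give
missing statistics, constant features are excluded from selection, and
folds that lose a class are skipped and logged.

## Known limitations

* Feature names and the reconstruction of the under-specified head and
  eye blocks (diversity rate, change rate, the three head-rotation
  categories) are deterministic and documented, but other readings of the
  same inventory exist; the block *lengths* are pinned, the semantics of
  a handful of entries are a choice.
* The minimum stream-coverage fraction for a segment to count as recorded
  (default 0.8 in `align_autonomic()`) is not externally specified.
* The generator's effect sizes are free parameters; reported accuracies
  on synthetic cohorts characterise the pipeline, not any real
  population.
* No smoothing, filtering or artifact correction is applied beyond
  missing-frame handling, and no temporal/sequence features beyond the
  functionals are extracted.
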