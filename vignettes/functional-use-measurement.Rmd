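---
title: "Measuring functional upper-extremity use from wrist accelerometry"
author: "armuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring functional upper-extremity use from wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armuse)
```

## The measurement problem

After a stroke, the weaker (paretic) arm is often *capable* of more than it
is actually *used for* in daily life. Clinic scales such as the Action
Research Arm Test (ARAT, 0–57) or the upper-extremity Fugl-Meyer (UEFM,
0–66) measure capacity under instruction; self-reports such as the Motor
Activity Log (MAL, 0–5) measure perceived use and carry the usual
self-report biases. Bilateral wrist accelerometry can observe use directly
and continuously, but raw movement is not the construct of interest:
walking swings both arms without either doing anything functional. The
legacy summary — activity *counts* per epoch, with movement declared when
counts exceed 2 — is blind to this distinction and inflates paretic-limb
use estimates.

This package measures **functional** use: for each limb, the fraction of
classifiable time spent in task-serving movement, and per subject the

$$\text{use ratio} = \frac{p_{\text{paretic}}}{p_{\text{less-affected}}},
\qquad p = \frac{\#\text{functional}}{\#\text{functional} + \#\text{non-functional}}.$$

The ratio is deliberately **not clipped at 1**; paretic-dominant use
occurs and is informative. Unknown (unclassifiable) time is excluded from
both numerator and denominator — the ratio is defined over behavior that
could be classified, a convention this package states explicitly because
the alternative (counting unknowns in the denominator) changes the scale.

## Pipeline and its assumptions

**Synchronization.** Sensors and video run on different clocks. The
donning/doffing protocol shakes both sensors five times along z, leaving
five large reversal peaks per train in the z signal. Detection is a strict
local maximum of z above 2 g with a 100 ms refractory gap, searched in the
leading/trailing 10 s; the 2 g threshold sits between the ≤1.5 g activity
content and the 4 g pulse amplitude. The ten paired landmarks feed a
least-squares **affine** map `sample = a + b·frame`: the slope term absorbs
consumer-sensor clock drift over long sessions; an offset-only fit (slope
fixed at the nominal 50/30 rate ratio) is available when drift can be
assumed away. A residual RMS above 2 sensor samples rejects the pairing as
inconsistent. Video-side marks are accepted as possibly fractional frame
positions (a CSV of `train,frame_index`), keeping the human marking step
explicit.

**Annotation.** Frame codes follow the FAABOS scheme; the published code
table is external to this package, so the 5→3 collapse ships as a
configurable default (two lowest codes → non-functional, two task-engaged
codes → functional, remainder and the unscored sentinel → unknown) and is
echoed into the run manifest. Annotators merge by **strict majority**;
frames with no strict majority become unknown rather than being dropped,
preserving timeline alignment at the cost of a conservative bias. Sensor
samples take the label of the nearest video frame under the time map;
samples outside video coverage are unknown.

**Blocks and features.** Non-overlapping 2-s blocks (100 samples at 50 Hz)
are anchored at the first sample after the leading pulse train (plus a
0.5 s guard), so the block grid is deterministic and sync regions never
enter blocks. A block is labeled functional or non-functional only when
that class strictly exceeds 90 % of *all* samples in the block — unknown
samples count in the denominator but can never win, which is the
conservative reading of the purity rule; everything else is *ambiguous*.
Ambiguous blocks are never trained on. The 17 features per block are mean,
variance, maximum and minimum of each axis and of the vector magnitude,
plus the Shannon entropy of the magnitude sequence. Conventions chosen
here and fixed: population variance (n denominator); entropy on the
**magnitude** sequence (orientation-invariant) over 16 equal-width bins
spanning the block's own [min, max], in bits, with a constant block
defined as 0; the feature order is part of the model contract
(`featureNames()`).

**Classification.** One random forest per subject and limb: 100 trees,
⌊√17⌋ = 4 candidate features per split, unlimited depth, minimum leaf 1 —
standard forest defaults, config-exposed, since the measurement claim is
pipeline-level rather than hyperparameter-level. Stratified 5-fold
cross-validation over unambiguous blocks (per-fold class proportions
within one block of the global proportion); each unambiguous block is
predicted exactly once by a model that never saw it. Ambiguous blocks are
predicted by all five fold models and resolved by majority — they
contribute to the use-ratio estimate (which should cover all behavior) but
never to the confusion metrics (they have no clean block-level truth). A
class with fewer blocks than folds aborts with `insufficient class
support`. All fold assignments and forests are seeded; identical inputs
and seeds reproduce identical predictions.

**Count baseline.** Genuine actigraphy counts are proprietary, so the
baseline is a documented proxy: gravity-removed vector magnitude,
band-passed 0.25–2.5 Hz (Butterworth order 2, zero-phase), rectified,
integrated per 1-s epoch, gain 1 count per g·sample. The gain was
calibrated once so that rest-level noise (SD 0.02 g) integrates below the
conventional >2-count threshold while gait-amplitude oscillation
integrates above it; it is a baseline approximation, not a claim of
equivalence to any vendor algorithm.

**Validity suite.** Pearson correlations use pairwise deletion (per-row n
is reported) with Fisher-z intervals — the method reproduces the published
ARAT and UEFM interval bounds from their r and n, which is the analytic
anchor of the test suite. The nine-hole peg time is entered raw (seconds),
so its correlations and loadings are expected negative. Bland–Altman
reports both the conventional limits of agreement (bias ± 1.96·SD of
differences) *and* the t-based confidence interval of the bias itself,
distinctly labeled, because the two are easily conflated. Factor analysis
is a principal-component decomposition of the correlation matrix
(listwise-complete rows), eigenvalue > 1 retention in auto mode or a
forced count, varimax rotation with Kaiser normalization, and per-factor
signs normalized so the largest-magnitude loading is positive.

## Numerical choices worth knowing

- `stats::varimax` started from the identity can stall in a local optimum
  of the rotation criterion (observed on clean two-block loading
  patterns). Rotation therefore tries the identity plus eight fixed
  orthonormal starting rotations and keeps the solution with the highest
  criterion value; this is deterministic and preserves communalities to
  machine precision.
- The factor step only needs the eigendecomposition, so near-zero
  determinants (small cohorts of highly correlated measures) are fine; the
  error path triggers only on constant variables or when a forced factor
  count reaches into null eigenvalues.
- Recording validity requires ≥2 samples (enough to infer the sampling
  rate); the one-block minimum is enforced where it matters, in
  `partitionBlocks`.
- Ties in the ambiguous-block cross-fold majority cannot occur with an odd
  fold count; with even counts the first class in the fixed level order
  (functional) wins — documented rather than randomized, to keep runs
  reproducible.

## What the simulator emulates — and what it does not

Sessions are seeded epoch schedules rendered as signal. Gait epochs occupy
shared timeline positions (whole-body movement moves both wrists at once):
a common 1.5–2 Hz sinusoid plus harmonic with limb-specific phase, ~0.25–
0.45 g — deliberately above the count threshold, which makes the count
baseline's overestimation reproducible. Functional epochs are trains of
Gaussian-windowed 0.5–3 Hz bursts (~1 per 0.8 s so every 2-s block inside
an epoch sees burst energy), amplitude scaled by 1 − impairment on the
paretic limb; each limb's epochs are placed independently in the non-gait
gaps, so bimanual overlap occurs and the schedulability constraint is
per-limb. Rest is the 0.02 g noise floor plus gravity on z. Annotators
reproduce the collapsed truth with i.i.d. per-frame corruption and
re-express it as raw FAABOS codes, exercising the full collapse/merge
path.

The source study gives no distributional description of its sessions, so
the defaults here are declared choices, not inferences: 300 s schedulable
time (sessions scaled down from the ~30 min originals to keep full-cohort
runs interactive; cohort statistics are driven by the number of blocks,
which remains in the hundreds per limb), 20 % gait, less-affected
functional fraction 0.45, paretic fraction 0.05 + 0.40·(1 − impairment),
impairment spanning 0.1–0.8, three annotators at 5 % frame error. Clinical
scores couple linearly to impairment (ARAT 57·(1−i) ± 4, UEFM
52.8·(1−i) + 10 ± 4, MAL 5·(1−i) ± 0.5, peg 30 + 250·i ± 15, clipped to
range). With these constants the synthetic battery is *more* tightly
coupled than real clinical data — cohort correlations come out near 0.95
where the study reports 0.6–0.9 — because a single latent severity drives
everything and the couplings are linear. That is intentional honesty about
a limitation: passing the recovery tests shows the pipeline preserves the
signal the simulator put in; it does not show that real stroke data are
this clean. Likewise the synthetic classes are more separable than real
wrist data (cross-validated accuracies here approach 1.0 versus ~0.91–0.95
on real recordings), the simulator makes no attempt at biomechanically
realistic trajectories, task-specific structure, sensor saturation, or
annotator biases that are correlated across frames.

## Test and acceptance problem sizes

The property suites run on: a 120 s gait-heavy subject (module tests), a
12-subject cohort at 300 s per session (parameter recovery: ML-estimated
vs true use ratios r ≥ 0.95, per-subject per-limb cross-validated accuracy
≥ 0.85), a 10,000-frame annotator track (binomial consensus-error check),
1,000 random blocks against a brute-force feature oracle, and n = 200
Gaussian batteries for the factor-analysis and Bland–Altman coverage
properties. `scripts/acceptance.R` runs a 31-subject cohort with 10
secondary batteries masked and one additional missing peg time, mirroring
the study's battery sizes (per-row n = 31/21/20).

## Known limitations

- Subject-specific models only: every new subject needs annotated video to
  train on. Generalizable (leave-one-subject-out) modeling is out of scope.
- The count proxy is a stand-in; absolute count values are not comparable
  to vendor counts, only the threshold behavior is.
- Block-denominated ML proportions versus sample-denominated video
  proportions differ slightly by construction; both conventions are
  recorded in the output rather than reconciled.
- The published MAL and nine-hole-peg interval bounds are not reproducible
  by the Fisher-z construction under their stated n; the package makes no
  attempt to match them and reports its own Fisher-z intervals throughout.
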