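---
title: "Methods: models, defaults, and design choices in moveprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults, and design choices in moveprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`moveprof` turns multi-site IMU recordings of repetitive exercise into two
assessments: movement identification (adherence) and a three-level
proficiency grade per movement. This vignette explains the models behind
each stage, every tunable default with its units and rationale, what the
synthetic-data generator does and does not emulate, and the numerical
choices a maintainer would want to know about. It states no empirical
result beyond what the package's tests and `scripts/acceptance.R` compute.

## 1. Data model

A *session* is one subject's recording: 13 placements (chest, abdomen,
sacrum, and bilateral upper arm, wrist, thigh, shank, ankle), each a
synchronized 9-axis series in hardware units (g, deg/s, gauss) at a
nominal 100 Hz; movement markers in seconds; and one gross-competency
score per (movement, side), 0–5 in 0.5 steps. Scores below 3 are *low*,
scores in [3, 4) *medium*, 4 and above *high*. Readers are total
validators: any range, monotonicity, granularity, or completeness
violation is a typed error, never a silent clip — with 13 devices, silent
coercion of one mis-calibrated channel would contaminate 29 features
before anyone noticed.

Time is stored in seconds (not sample indices) so markers survive the
100 → 32 Hz rate change.

## 2. Signal conditioning

All analysis runs at a working rate of 32 Hz. Movement content in this
protocol lives below ~4 Hz, so 32 Hz retains a comfortable margin while
cutting compute 3×.

* **Resampling** (`resample_series()`): a Kaiser-windowed-sinc FIR
  anti-alias filter (cutoff 0.45 × target rate, β = 8) applied at the
  original rate, followed by cubic-spline evaluation on the target grid.
  On tones this is transparent (errors ~1e-5); content above the target
  Nyquist is suppressed below 1e-4. We chose this factorization over a
  classical polyphase implementation after finding the available
  polyphase routine inaccurate at this ratio (tone amplitude errors of
  several percent); the anti-alias guarantee is identical.
* **Filtering** (`lowpass_filter()`, `bandpass_filter()`): 4th-order
  Chebyshev Type I designs, 0.5 dB passband ripple, applied
  forward–backward (zero phase, so segmentation timing is not skewed;
  effective ripple doubles to ~1 dB, documented in the tests'
  tolerances). The low-pass (≤ 4 Hz) keeps gravity and is the input to
  orientation features; the band-pass (0.1–4 Hz) removes the DC
  component and feeds the dynamic features. The band-pass defaults to a
  cascade of a 4 Hz low-pass and a 0.1 Hz high-pass rather than a single
  8-pole band-pass design: with band edges spanning a 40:1 frequency
  ratio, the single design is numerically ill-conditioned in
  transfer-function form (DC residuals of several percent on constant
  input), while the cascade leaves < 0.1%. The single design remains
  available (`band.cascade = FALSE`). Filter family and ripple are
  config keys (`cheby.family`, `cheby.ripple_db`).
* **Edge handling**: reflect-padding of one settling length (three time
  constants of the lowest band edge) before any filtfilt, so block
  boundaries carry no start-up transient.

## 3. Repetition segmentation

Markers cut the session into movement blocks. Within a block,
repetitions are separated by brief low-velocity pauses. True zero
crossings of velocity never occur in noisy data, so the pause criterion
is operationalized on a smoothed angular-velocity envelope: the low-pass
filtered Euclidean norm of the gyroscope, averaged over the two wrists
(the upper limbs move in every movement of this repertoire; the source
placements are configurable per movement).

Defaults: threshold 10 deg/s, minimum pause 0.2 s, minimum repetition
1.0 s. Boundaries are placed at pause midpoints (envelope minima are an
alternative, `boundary = "minimum"`). Sub-threshold runs touching the
block edges are lead-in/lead-out quiet standing, not inter-repetition
pauses — they cut nothing. If a caller supplies an expected repetition
count and the automatic count disagrees, the result is *flagged for
review* rather than forced; a boundary-override table
(`segment_session(..., overrides = )`) plays the role of the manual
confirmation step such protocols include.

## 4. The 378-feature registry

The published description of this feature space names the families and
the total; the exact composition is not recoverable. The default
registry (`feature_registry()`) is therefore a documented
reconstruction, data-driven (YAML-exchangeable) so alternatives drop in:

* 312 spectral: 13 sensors × {accel, gyro} × {x, y, z} ×
  {low-pass, band-pass} × {dominant frequency, mean frequency};
* 52 orientation: 13 sensors × {mean pitch, mean roll, pitch range,
  roll range} from the low-pass accelerometer, with
  pitch = atan2(−ax, √(ay² + az²)), roll = atan2(ay, az);
* 14 cross-correlation: peak coefficient and signed lag of the band-pass
  gyroscope magnitude for 7 pairs (all four ankle–wrist pairs,
  ankle–ankle, wrist–wrist, chest–sacrum), privileging inter-limb
  synchrony.

Spectra use a single-segment, Hann-windowed, zero-padded periodogram on
a 0.05 Hz grid (repetitions are a few seconds long; splitting them into
Welch segments would destroy frequency resolution). Degenerate inputs
(all-zero series, zero-variance cross-correlation, sustained sub-0.5 g
gravity) produce documented sentinels plus a flag count instead of NaNs.
The magnetometer is generated and stored but feeds no default feature.
A hash of the registry travels with every feature table and model
bundle; mixing artifacts from different registries is an error.

## 5. Selection and models

**mRMR** (`mrmr_rank()`): greedy MID variant — first pick maximizes
mutual information with the label; later picks maximize relevance minus
mean redundancy against the already-selected set. Continuous features
are discretized into equal-frequency tertiles (config). Constant
features get zero relevance and sink to the bottom rather than being
dropped. The greedy search runs to `max_rank` (default 40) and appends
the remainder by relevance — the tail of an mRMR ranking is never used
by the selection rule. The implementation is verified against an
independent exhaustive oracle in the tests.

**Feature-count rule** (`select_feature_count()`): train with an
increasing number of top-ranked features and keep the smallest count
whose score reaches 95% of the full-set score. Two estimation details
matter at small cohort sizes:

* the score is a subject-grouped 3-fold cross-validated micro F1
  (`grouped_cv_evaluator()`), not an out-of-bag estimate — OOB mixes a
  subject's repetitions across trees, systematically overstating tiny
  feature sets that memorize subjects;
* the raw curve fluctuates a few percent between adjacent `k`; under an
  mRMR ordering more features never genuinely hurt, so the curve is
  isotonic-regularized (non-decreasing) before the rule is applied.
  Without this, a single upward fluctuation at small `k` truncates the
  feature set spuriously. The raw curve is kept in the result.

The curve may be evaluated on a sub-grid of `k` for economy; the
reference is always the full ranking.

**Forests**: 100 trees (`randomForest`), other hyperparameters at
library defaults, training seed recorded in the bundle. Left/right
variants of a movement are one class; side stays metadata.

**Hierarchy** (`hierarchical_scorer()`): movement prediction routes each
repetition to that movement's 3-class proficiency forest — routing uses
the prediction, never the truth, which is what makes the
misrouting-robustness analysis (`misrouting_robustness()`) meaningful.
Class imbalance is left as observed; no resampling or reweighting.
A movement with a single observed grade trains a degenerate
constant-grade model and is flagged.

**Aggregation** (`aggregate_majority()`): the subject-movement grade is
the modal repetition grade; ties break toward the *lower* grade — in a
balance-training context the conservative error is understating
proficiency, and the tie rule must be deterministic.

## 6. Evaluation

`make_loso_plan()` builds deterministic leave-one-subject-out folds;
repeats (reference protocol: 20) differ only through the training seeds
handed to the forests — the only reading under which repeated LOSO
produces a spread. Micro F1 (pooled accuracy for single-label tasks) is
reported at repetition level and after majority voting; undefined
precision/recall is reported as 0 with a flag, never NaN. With
`selection.mode = "nested"` (default) ranking and the 95% rule run
inside every training fold; `"paper"` mode performs one global selection
first, reproducing protocols that accept that leakage.

Sammon projections (`sammon_project()`) start from the PCA scores and
descend with step halving (tolerance 1e-6, ≤ 500 iterations, duplicate
points epsilon-jittered and flagged); the final stress never exceeds the
initialization's.

## 7. The synthetic study

Real cohorts of this kind cannot be redistributed, so the package
generates one with the statistical structure the pipeline assumes. Each
movement archetype is a stack of phase-locked harmonics: a fundamental
(repetition tempo, 0.155–0.40 Hz across the six movements), per-site
gyroscope amplitudes weighted by limb emphasis, a per-site posture
(gravity direction) with movement-specific tilt, and per-limb phase
offsets encoding coordination. The accelerometer reads gravity through
the time-varying pitch/roll, the gyroscope carries the oscillation under
a smooth per-repetition envelope (ramps capped at 0.4 s so motion onsets
stay sharp), and the magnetometer sees a constant earth field through
the same rotation. Two archetypes (the GST/WHLC analogs) are built
deliberately confusable by interpolating one toward the other
(`overlap = 0.6` by default, a config parameter).

Inter-subject structure — what LOSO actually tests — comes from subject
random effects: lognormal tempo and amplitude multipliers (σ = 0.06 and
0.04), per-site posture offsets (σ = 2.5°), per-site phase offsets
(σ = 0.15 rad), plus rep-to-rep postural sway (σ = 2°). The sway matters
more than it looks: without it, per-repetition orientation features have
almost no within-subject variance, and a two-feature model can separate
the training subjects perfectly while failing on a held-out subject —
an effect the selection rule must be able to see in its own
cross-validation.

Proficiency grades degrade execution through four variability channels —
band-limited 2–6 Hz "jerk" noise, tempo jitter CV, amplitude CV, and
inter-limb phase noise — plus three mean-drift magnitudes (tempo,
amplitude, arm–leg timing), all strictly decreasing from low to high
grade (`proficiency_profiles()`). Crucially, *which* channels express a
movement's quality, and in *which direction*, is a property of the
movement (`grade_expression` in the archetype): a novice is shaky in the
balance-demanding single-leg movement but stiff and dynamically flat in
the flowing ones, drags one movement's tempo and rushes another's,
undershoots some amplitudes and overshoots others. This heterogeneity is
what makes movement-specific proficiency models genuinely better than
one pooled model — the pooled model's feature selection sees near-zero
marginal association for channels whose sign flips across movements —
mirroring the qualitative ordering such studies report. Grades are
assigned per subject-movement by largest-remainder rounding of the
configured proportions (default uniform thirds), so every grade is
represented in every movement.

What the generator does **not** emulate: biomechanically faithful
choreography, soft-tissue artifacts, sensor drift or bias, dropped
samples, magnetometer disturbances, and learning effects within a
session. Passing tests on this cohort therefore demonstrate that the
pipeline recovers structure *of the kind assumed*, at the configured
noise levels — not that it would reach the same numbers on any real
cohort.

## 8. Problem sizes and reproducibility

The default study is 8 subjects × 6 movements (bilateral except the
RTP analog) × 6 repetitions = 528 repetitions, evaluated with 3-repeat
LOSO; these sizes keep a full end-to-end run in the minutes range on one
core while leaving every phenomenon of interest visible (the tests and
`scripts/acceptance.R` use exactly these sizes). Every stochastic step —
generation, fold seeds, forest training, evaluator splits — derives from
one master seed, and the determinism test requires byte-identical
outputs from repeated runs of every pipeline stage.

## 9. Known limitations

* The feature registry is a reconstruction; only its families and total
  are anchored.
* The segmenter assumes inter-repetition pauses exist (≥ 0.2 s below
  10 deg/s at the wrists); continuous flowing execution without pauses
  would need the per-movement envelope override table.
* Per-movement proficiency models see few subjects per grade at the
  default cohort size; their fold-to-fold spread is correspondingly
  large.
* Sub-repetition (phase-level) analysis and streaming segmentation are
  out of scope.
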