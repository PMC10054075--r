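---
title: "Estimating VO2max from exercise and recovery heart rate variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating VO2max from exercise and recovery heart rate variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Maximal oxygen uptake (VO2max, mL/kg/min) is the criterion measure of
cardiorespiratory fitness. Measuring it directly requires a graded exercise
test (GET) with breath-by-breath gas analysis — accurate but obtrusive.
Heart rate is physiologically coupled to oxygen uptake during exercise, and
heart rate *variability* (HRV) reflects autonomic state: vagal tone withdraws
with intensity and re-engages during recovery, faster in fitter subjects.
`vo2hrv` implements a pipeline that estimates VO2max from the heart-rate side
alone: beat-interval cleaning, HRV feature engineering over the exercise and
recovery phases, hybrid feature selection, regression under subject-wise
cross-validation, and a post-modelling analysis of deviant subjects whose
maximal treadmill speed is inconsistent with their measured fitness.

```{r setup}
library(vo2hrv)
```

## Preprocessing and quality control

RR intervals are cleaned in three steps, none of which changes the number of
beats:

1. **Range filter.** Intervals outside 300–2000 ms (inclusive bounds:
   boundary beats are physiologically plausible) are flagged as outliers.
2. **Karlsson ectopic detection.** An interior beat is ectopic when it
   deviates from the mean of its adjacent intervals by strictly more than
   20%. Published variants of this rule differ; we adopt the
   adjacent-interval-mean form, skip neighbours already flagged by the range
   filter, and compare endpoints to their single neighbour. The 20%
   threshold is a config constant (`karlsson_threshold`).
3. **Linear interpolation.** Every flagged beat is replaced by linear
   interpolation over beat index between the nearest unflagged neighbours;
   edge runs take the nearest unflagged value. Beat times are rebuilt from
   the corrected intervals.

The chain is idempotent, and on synthetic series with injected artifacts
(per-beat spike rate 0.005, ectopic rate 0.001) it flags essentially all
injected beats while leaving RMSSD within a few percent of the artifact-free
value — both properties are asserted in the test suite.

Segments then pass four quality rules: HR/VO2 phase coherence (Spearman
correlation of HR and VO2 over exercise must not be negative — "out of
phase" is not otherwise defined, so the sign of the rank correlation is the
operationalisation, with threshold 0 as a config constant), no consecutive
HR step above 30 bpm after cleaning, exercise duration of at least 300 s,
and no missing HR/VO2 samples. The duration rule applies to exercise only:
the recovery window is fixed at 3 minutes by the recording protocol, so a
5-minute minimum would discard every recovery segment.

## Feature engineering

The exercise phase yields a 101-feature vector; recovery yields 30. The
composition is fixed by a *manifest* (`feature_manifest()`), so changing the
composition never touches extraction code. Families:

* **Metadata** (6): age, gender, height, weight, BMI, protocol type.
  Gender and protocol are encoded 0/1 (male = 1, incremental = 1) so they
  participate in correlation and distance computations.
* **Session summaries**: maximal speed, exercise duration, max/min/mean/SD
  of HR, HR reserve.
* **Time domain** (12 + 12 slopes): Mean/Median NNI, SDNN, SDSD, RMSSD,
  CVNNI, CVSD, NNI/PNNI at 20 and 50 ms, Range NNI. Sample-SD (`n - 1`)
  conventions throughout; `PNNI x` uses the `n - 1` successive differences
  as denominator. The NNI thresholds are absolute milliseconds, so these
  counts are deliberately not scale-equivariant.
* **Frequency domain** (4 + 4 slopes, exercise only): VLF (0–0.04 Hz), LF
  (0.04–0.15 Hz), HF (0.15–0.4 Hz) and their sum. The NN series is cubic-
  spline resampled to 4 Hz, linearly detrended, and a Welch periodogram
  (Hann window of min(256 s, segment), 50% overlap) is integrated by
  trapezoid over each band. Welch was preferred over Lomb–Scargle for
  determinism on the uniform grid. The 3-minute recovery segment is too
  short for reliable spectral estimates, so frequency features are
  undefined there (requesting them is an error, not a silent NA).
* **Nonlinear** (6 + 6 slopes): Poincaré SD1/SD2 (via the
  successive-difference identities `SD1^2 = var(diff)/2`,
  `SD2^2 = 2 SDNN^2 - SD1^2`), their ratio, CSI, CVI, and the short-range
  DFA exponent alpha1 (4–16 beat boxes; alpha2 uses 16–64 beats and is
  reported by `nonlinear_features()` but excluded from the sliding-window
  slope family, where 60-s windows cannot support 64-beat boxes).
* **Windowed DFA slopes** (6 exercise / 5 recovery): alpha1 on 60-s windows
  stepping 15 s; `DFA Slope h` is the least-squares slope of alpha1 against
  window midpoint over midpoints within `[0, h]`, `Ins DFA Slope h` the mean
  finite-difference slope. The midpoint convention is what makes the 60-s
  horizon well defined (three windows with midpoints 30/45/60 s).
* **Speed/time/HR landmarks**: per quartile of maximal speed, total time and
  maximal HR — first-crossing times, HR-vs-time slopes, speed–HR
  correlations, quartile-max HR; plus dwell times in 10%-of-max-HR zones
  and 20%-of-max-speed zones.

Sliding-window slopes use 60-s windows stepping 30 s (window sizes are not
dictated by the protocol; they are config constants). Frequency-domain
slopes instead use 150-s windows stepping 30 s: the spectral estimator
requires at least 120 s of beats, and a 120-s window's *beat span* falls
just short of its nominal length, so the slope window must exceed the
minimum with margin.

Missing cells (a landmark span with fewer than 3 samples, a window too
short for DFA) are explicit NAs, median-imputed per training fold during
modelling — imputation statistics never leak from test subjects.

## Feature selection

Three selectors, all operating strictly on training folds:

* **Correlation filter** (`"corr"`): rank by absolute Spearman correlation
  with VO2max, then walk the ranking top-down keeping a feature only if its
  absolute Spearman correlation with every kept feature is at most 0.7
  (the conventional multicollinearity threshold). Removed features record
  which kept feature displaced them.
* **Mutual information filter** (`"mi"`): identical pruning, but ranked by
  a Kraskov k-nearest-neighbour MI estimate (k = 3, nats), with the
  Ross discrete–continuous variant for features with at most 5 distinct
  values (gender, protocol). A microscopic seeded jitter breaks ties, so
  the ranking is deterministic. Pruning still uses Spearman correlation.
* **Greedy forward–backward wrapper** (`"greedy"`): forward steps add the
  feature minimising 5-fold cross-validated RMSE of the chosen model on the
  training partition; backward steps remove the feature whose removal most
  decreases it; the phases alternate until a full cycle changes nothing.
  Improvements must exceed `tol = 1e-6` RMSE, ties resolve by manifest
  order, and the inner fold assignment is fixed once per call — the
  procedure is fully deterministic and terminates (each accepted step
  strictly decreases a bounded metric). Scoring by internal
  cross-validation rather than a held-out testing error keeps subject-wise
  independence intact end-to-end.

## Models and evaluation

Multiple linear regression is solved in closed form by QR least squares —
for a full-rank design this is the exact minimiser of the mean-squared-error
objective that gradient descent approaches asymptotically, so the closed
form is preferred for determinism (the equivalence is asserted against a
gradient-descent implementation in the tests). Rank-deficient designs fall
back to the minimum-norm solution with a warning. Random forests use
`ranger` (split rule: SSR/variance; hyperparameters: number of trees,
maximal depth, minimal node size to split). Support vector regression uses
the Gaussian-RBF epsilon-insensitive formulation via `e1071` (hyperparameters
C, gamma, epsilon). Features are z-scored with training statistics for MLR
and SVR; forests are scale-invariant and run on raw features.

Default grids — C in {0.1, 1, 10, 100}, gamma in {1e-3, 1e-2, 0.1, 1},
epsilon in {0.1, 0.5, 1}; trees in {100, 300}, depth in {3, 5, 10,
unbounded}, min-node in {2, 5, 10} — are config constants; the protocol
prescribes exhaustive grid search with 5-fold inner cross-validation, ties
broken by grid order.

Evaluation is 10-fold *person-independent* cross-validation: subjects are
randomly permuted into ten near-equal folds and no subject ever appears on
both sides of a split. Selector and hyperparameter decisions are recomputed
inside every training fold. Metrics (Pearson R, RMSE, MAE, MAPE) are
reported both pooled over the concatenated out-of-fold predictions (primary,
since per-fold R is unstable at 10% fold sizes) and as per-fold means.

## Deviant-point analysis

Maximal speed is both highly ranked by every selector and monotonically
linked to VO2max, so the (maximal speed, measured VO2max) plane is where
inconsistent sessions show up. Each subject's deviance score is the mean
Euclidean distance to its k = 5 nearest neighbours after z-scoring both axes
(speed in km/h and VO2max in mL/kg/min are not commensurable); a subject is
deviant when its score exceeds the upper Tukey fence Q3 + 1.5 IQR. Both k
and the fence are config defaults — the detection rule only promises "a
predefined threshold", and the Tukey fence is scale-free and deterministic.

Two re-evaluation protocols:

* **Case 1** removes flagged subjects everywhere and reruns the standard
  experiment — the cleaned-benchmark view.
* **Case 2** mimics deployment: test folds are stratified so they keep the
  cohort's reliable-to-deviant ratio, and deviants are removed from the
  training side only. Because identifying a deviant requires the measured
  VO2max, which at deployment exists only for training subjects, the
  training-side flags are recomputed from the training points alone; a
  training subject is dropped only when that train-only detection agrees
  with the cohort-level flag (this also guarantees that with no deviants at
  all, Case 2 reduces exactly to the baseline experiment — fold-shaped gaps
  in the point cloud cannot evict reliable subjects).

Simulations reproduce the qualitative pattern the protocols are designed to
show: Case 1 lowers pooled RMSE relative to baseline in essentially every
replicate, and Case 2 gives most of that improvement back (its RMSE is at
least Case 1's, and typically slightly above baseline — a model trained
only on reliable subjects pays on the unpredictable deviant test points).

## The synthetic cohort generator

Real GET recordings are not shippable test fixtures, so `generate_cohort()`
produces cohorts with the statistical structure the analysis assumes, plus
ground truth. Per subject: age uniform on 10–63 years; true VO2max is a
gender baseline (55 male / 47 female mL/kg/min) minus 0.25 per year past
age 20 plus N(0, 6) noise, clamped to 25–75; maximal speed is
`4 + 0.22 * VO2max` km/h plus N(0, 0.8); maximal HR follows the Tanaka-style
law `208 - 0.7 * age`. Traces: the step protocol starts at 5 km/h and adds
1 km/h per minute (a final minute at the exact maximal speed); the
incremental protocol ramps linearly over the same duration. HR follows
first-order kinetics (tau = 30 s) toward a target rising with relative
speed to the 0.9 power; recovery decays exponentially toward rest + 20 bpm
with time constant `80 - 0.6 * VO2max` s (floor 20 s) — fitter subjects
recover faster. VO2 is affine in the HR reserve fraction plus N(0, 1). The
beat-level RR series integrates 60000/HR plus a variability term whose scale
`sigma0 = 2 + 0.25 (VO2max - 25)` ms shrinks by 80% from rest to maximal
intensity (a 5:1 ratio, the vagal-withdrawal signature) and re-expands
linearly over recovery, with 0.1 and 0.3 Hz oscillatory components standing
in for baroreflex and respiratory modulation.

Every constant above is deliberate plumbing, not an estimate: the values
make the qualitative physiological claims the pipeline relies on — HR–VO2
linearity, HRV shrinking with intensity, faster recovery and higher HRV
with fitness, a noisy monotone fitness–speed link — literally true in
simulation, each addressable as a named constant. A configurable fraction
of subjects (default 5%) is *deviant*: their maximal speed is redrawn
uniformly over the cohort's speed range, rejection-sampled outside a
3-sigma margin of the speed their fitness would predict, because a deviant
is by definition a point off the primary cluster — a redraw that lands back
on the cluster would be deviant in name only. Spike artifacts (outside
300–2000 ms) and ectopic pairs (a premature beat with compensatory pause:
`(d, d') -> (0.5 d, d' + 0.5 d)`, preserving total time) are injected with
recorded indices.

What the generator does *not* emulate: respiratory gas-exchange dynamics
beyond the linear HR link, circadian/thermoregulatory drift, motion-artifact
autocorrelation, or the heavy-tailed inter-subject heterogeneity of real
athlete cohorts. Passing tests therefore demonstrate that the pipeline
recovers structure *of the kind it assumes*, at realistic noise levels — not
that it attains any particular accuracy on real recordings. On the synthetic
cohorts the fitness signal in the RR variability scale is strong, so pooled
R values run well above what heterogeneous real data yield.

## Numerical choices and problem sizes

Determinism is enforced everywhere: every stochastic operation takes a seed,
child seeds are derived arithmetically (kept below 2^31), inner fold
assignments are drawn once per call, and all tie-breaks are by declared
order (manifest order for selectors, grid order for hyperparameters).
Degenerate inputs propagate as typed conditions (config, format, integrity,
too-short) or as explicit NAs where the quantity is simply undefined
(constant series for CSI/CVI, negative SD2 squared, DFA on constant input).

The test-suite problem sizes are the package's own choices, set to exercise
each claim at meaningful power: single-run parameter recovery on an
800-subject cohort; 20-replicate directional comparisons (greedy vs no
selection) on 120-subject cohorts, where 101 features against ~108 training
subjects is precisely the overfitting regime selection is meant to address;
deviant-protocol comparisons on 150-subject cohorts with the 9-feature base
manifest, since the deviant mechanism acts on maximal speed and the base
feature set is the one directly affected; artifact-recovery checks with 50
injection replicates on a single fixed trace.

## Known limitations

* Box-counting DFA with per-box linear detrending has a finite-size bias at
  the short scales the alpha1 convention prescribes: for uncorrelated input
  the exact expectation `E[F^2(n)] = sigma^2 (n^2 - 4) / (15 n)` makes the
  fitted slope over integer scales 4–16 equal 0.583 rather than the 0.5
  asymptote (integrated noise is unaffected: slope 1.50). This is a property
  of the estimator itself, shared by standard implementations; alpha1 values
  remain comparable across subjects but should not be read as unbiased
  estimates of the asymptotic scaling exponent.
* The spectral estimator assumes the cubic-spline 4 Hz resampling is benign;
  very irregular (heavily ectopic) segments should be cleaned first, which
  the pipeline does, but pathological residual patterns could still bias
  band powers.
* `SD2/SD1` and CSI are identical by construction; both names are kept for
  manifest compatibility and the collinearity pruner removes one of them.
* The public-repository session reader is a best-effort column matcher; the
  deposited layout's exact headers are not normative, so that adapter is
  isolated behind `read_session(layout = "physionet_treadmill")`.
* MAPE assumes strictly positive targets, which VO2max satisfies.
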