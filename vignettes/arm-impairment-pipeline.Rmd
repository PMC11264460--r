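---
title: "From landmark traces to ordinal impairment scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From landmark traces to ordinal impairment scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gaitarm assesses arm movement abnormality during walking from 2D landmark
traces produced by a marker-less pose estimator. This vignette is the
package's own account of the method: the model at each stage, the
assumptions it leans on, the tunable parameters and why their defaults are
what they are, what the synthetic data generator does and does not emulate,
and the design decisions that were genuinely open.

## The measurement model

The input is a time series of eight landmark observations
$(x, y, \ell)$ — pixel coordinates and a detector likelihood — for the
left/right shoulder, elbow, wrist and hip, filmed by a fixed frontal camera
while the subject walks toward it. Three assumptions shape everything
downstream:

* **The frontal plane is informative.** Held elbow flexion, shoulder
  abduction and reduced arm swing all project visibly onto the camera
  plane. Sagittal-plane detail (e.g. the direction of swing) does not, so
  all joint angles are *unsigned*, computed as
  $\theta = \arccos\!\big(\hat u \cdot \hat v\big)$ in $[0^\circ, 180^\circ]$.
* **Approach changes scale, not shape.** As the subject nears the camera,
  every inter-landmark pixel distance grows by a common factor. Angles are
  invariant to translation and uniform scaling, which is why angle summary
  statistics — not raw pixel quantities — are the features.
* **Landmark noise is mostly single-frame.** Pose estimators produce
  isolated mislocalizations and confidence drops; a three-point median
  filter on each coordinate series removes single-frame spikes without
  attenuating the swing signal (~1 Hz at 30 fps). Joint-angle series are
  deliberately not filtered, so filtering acts once, on the raw
  measurements, not twice.

## Trimming to the walking portion

A trial starts with the subject standing (stationary scale) and ends with
landmarks leaving the image as they come too close to the camera. Both ends
are trimmed automatically.

**Onset.** The monitored body widths (shoulder–shoulder and hip–hip pixel
distances) are three-point median filtered; the onset is the first frame at
which either width exceeds its baseline — the median over the first
`baseline_window = 10` frames — by `rise_fraction = 5%`, sustained for
`confirm_frames = 3` consecutive frames and confirmed by the median width
over the following `confirm_window = 10` frames.

Two robustness devices extend the plain relative-rise rule, both vanishing
on noiseless input:

* the threshold is lifted by `noise_guard = 3` robust standard deviations
  (MAD of the detrended baseline widths), so jitter alone cannot cross it.
  With ~1.5 px landmark jitter the raw 5% rise on a ~44 px hip width is
  about one noise SD — an unguarded detector false-triggers on roughly half
  of realistic trials;
* a linear fit over the baseline window detects traces that start
  mid-walk: if the fitted rise across the window itself exceeds the
  threshold (plus `noise_guard` standard errors of the fitted slope), the
  onset is the first frame.

The detection delay this buys is bounded and small: with scale growth $g$
per frame the guard adds roughly $\text{guard MAD}/(g\,\bar w)$ frames —
around a third of a second at the defaults — and the stationary prefix it
protects against mis-trimming is many times longer.

**End.** The trial ends at the first run of *strictly more than two*
consecutive frames in which any single landmark is lost, where lost means
likelihood below `likelihood_threshold = 0.6` or a non-finite coordinate.
Two lost frames are tolerated; three are not. The threshold value follows
common pose-estimation practice; the loss rule needs no tuning because it
is combinatorial.

Segments shorter than `min_retained_frames = 20` abort the trial: below
about two-thirds of a second there is no swing cycle to summarize.

## Angles and features

Per retained frame: the elbow angle at the elbow vertex between the
elbow→wrist and elbow→shoulder segments (180° = fully extended, matching
clinical goniometry, so "peak flexion" reads as a low minimum); the
shoulder angle between shoulder→elbow and the per-frame trunk axis, the
unit vector from the shoulder midpoint to the hip midpoint (0° = arm
hanging, 90° = horizontal). The trunk axis is recomputed every frame rather
than averaged, since trunk lean varies within a trial. Frames where any of
the four angles is degenerate (zero-length segment, coincident midpoints)
are dropped from all four series jointly to keep them aligned.

Each series is reduced to max, min, mean, sample SD ($n-1$), Fisher
skewness and excess kurtosis (population moments inside the ratios, the
default of the major scientific stacks) — $4 \times 6 = 24$ features in a
fixed, documented column order. A constant series gets skew = kurtosis = 0
by convention rather than 0/0. The label is the **median** of the
assessors' integer scores: for three assessors the median is itself one of
the given ordinal values, which an arithmetic mean would not be. An even
assessor count can give a half-integer median; it is rounded *down* (toward
less impairment) with a warning, a conservative convention that should not
arise in the intended three-assessor design.

## Classification and validation

A random forest classifies the 24 features into the five ordinal classes.
The forest treats classes nominally; the ordinal structure is honoured
downstream by the quadratically weighted agreement statistics. Nested
cross-validation separates tuning from assessment: five outer folds
estimate generalization, and within each outer training set a five-fold
inner grid search picks `num_trees` ∈ {100, 300, 500}, `max_depth` ∈
{unlimited, 5, 10} and `min_node` ∈ {1, 3, 5} by inner accuracy, with ties
broken by grid order so selection is deterministic. The standardizer (per
feature: remove mean, scale to unit variance; zero-variance features pass
through) is fitted on training rows only — the test fold of an outer
iteration influences nothing, and the fitted per-fold statistics are
retained in the result's `instrumentation` so the no-leakage claim is
asserted by tests rather than taken on faith.

Folds group by participant by default: each participant contributes two
trials, and splitting them across folds would let the model recognize the
person rather than the impairment. `by_trial` grouping is available for
designs without repeated participants. Forest fits go through ranger with a
fixed seed and one thread, so a fixed master seed reproduces fold
assignments, chosen hyperparameters and predictions exactly.

Chance performance is quantified by a Monte-Carlo permutation null: the
accuracy of the fixed prediction vector against label permutations, whose
mean is the collision probability of the two marginals. The package's
recovery claim is calibrated against this null (mean + 3 SD), not against
an arbitrary accuracy figure.

## Agreement battery

All comparisons between a prediction vector and a reference score vector:
exact accuracy (as a percentage), mean squared error, the tally of absolute
differences (whose zero bin recovers the accuracy exactly), quadratic
weighted Cohen's kappa with weights $w_{ij} = 1 - (i-j)^2/(k-1)^2$ over the
full five-category set (including unobserved categories), a one-sample
t-test of the signed differences with Cohen's
$d = \bar d / s_d$ (negative mean = under-prediction), one-way fixed-effects
ANOVA across prediction sets, and — after binarizing at score ≥ 2 =
impaired — recall, precision, accuracy and F1 from the 2×2 table.

The kappa standard error is a seeded nonparametric bootstrap over trials
(2000 resamples by default): assumption-free, and testable against the
large-sample formula of Fleiss, Cohen & Everitt, which is available behind
`se_method = "asymptotic"`. Degenerate cases are flagged rather than
silently zeroed: kappa is undefined when both raters use one identical
category; Cohen's d is reported as 0 with a flag when the differences are
constant; zero-denominator contingency ratios are `NA` with an `undefined`
flag. Tests are two-sided at $\alpha = 0.05$.

## The synthetic cohort generator

Real videos cannot ship with the package, so the generator produces
landmark traces with exactly the statistical structure the pipeline
assumes: a stationary prefix (60 frames at 30 fps), an approach phase in
which the pixel scale grows linearly at 1% of the initial size per frame,
sinusoidal frontal-plane arm swing (25° amplitude, 0.9 Hz, antiphase arms),
Gaussian landmark jitter (SD 1.5 px, within the 1.35–4.15 px error range
typical of pose estimators on HD video), isolated low-likelihood frames
(probability 0.01, kept non-adjacent so they never mimic a terminal loss),
and a scripted terminal wrist dropout at 92% of the trial.

Severity acts monotonically on one affected side: each step of severity
removes 22% of the swing amplitude and adds 12° of held elbow flexion and
6° of shoulder abduction. Severity-0 participants are symmetric. These
offsets are chosen to be large relative to jitter-induced feature noise
(a few degrees), so the feature→severity mapping is learnable by
construction — that is the point: the generator validates the machinery,
not the clinical effect size. Three simulated assessors score
$\mathrm{clip}_{[0,4]}(\mathrm{round}(s + \varepsilon))$,
$\varepsilon \sim N(0, 0.6)$, which produces the moderate inter-rater
agreement regime the median-label design is meant for (the median label
differs from the true severity on roughly a fifth of trials, which also
caps achievable prediction accuracy near 80%).

The default cohort mirrors the motivating study's design: 42 ABI and 34
control participants, two trials each, with all ABI trials and only five
control videos rated (controls would trivially score 0 and skew the
labelled data).

What the generator does **not** emulate: lower-limb kinematics, gait-cycle
structure (the swing is a pure projected sinusoid, not a biomechanical
model), correlated multi-frame detector failures, occlusion, camera
distortion, or rater biases beyond i.i.d. noise. Green tests therefore
demonstrate that the pipeline recovers the signal it is designed for under
its own noise model — not that any particular clinical accuracy will be
attained on real video.

## Numerical choices and degenerate inputs

* Dot products are clamped to $[-1, 1]$ before `acos`.
* Median-filter endpoints use edge replication (equivalently,
  `runmed(endrule = "keep")`), preserving length.
* Pose CSVs are written at six decimals; reading back reproduces
  coordinates at that precision.
* Inner-CV folds with a single training class are skipped inside the grid
  search; an outer training set with a single class proceeds with a
  warning.
* All seeds are set locally and the caller's RNG state is restored.

## Problem sizes

The test suite and the acceptance script run everything at desk scale,
chosen so the full suite completes in a couple of minutes: property suites
use 100–1000 random instances per invariant; the end-to-end recovery
cohort has 150 rated trials (45 ABI + 30 control participants, 60 rated
control videos) with the permutation null at 2000 resamples; bootstrap SEs
use 200–2000 resamples depending on context.

## Known limitations

* Unsigned angles fold at 0°: a swing crossing the trunk line is
  indistinguishable from its mirror, inflating the apparent mean shoulder
  angle at high swing amplitude. The severity signal survives folding, but
  individual angle traces should be read with this in mind.
* The elbow-vertex convention differs from the undirected-segment-axes
  reading (which would fold at 90°); the vertex convention was chosen to
  match clinical goniometry and is declared, not inferred.
* Whether folds should stratify by class, and whether final-model
  predictions should be out-of-fold or resubstitution, are genuinely open
  in this design; both modes exist (`nested_cv_evaluate()` vs
  `fit_final()` + `predict()`) and neither is asserted as canonical.
* The pipeline consumes landmark output; it neither trains nor audits the
  upstream pose estimator, and silently wrong-but-confident landmarks pass
  through undetected.
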