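---
title: "Classifying head movements from HMD rotation traces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying head movements from HMD rotation traces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headmov)
```

Virtual-reality head-mounted displays report the head's orientation at
every display refresh, which makes head movements — a central component of
how people explore a visual scene — directly measurable. There is no
agreed-upon definition of what constitutes "a head movement" in such a
stream, and different detection rules reach different conclusions about
when a movement began, how long it lasted, and how large it was. This
package implements five classification algorithms spanning the design
space (adaptive statistical thresholds, smoothed velocity thresholds,
sliding-window percentage rules, acceleration zero-crossing direction
coding, and supervised decision trees), together with the evaluation
machinery needed to compare any of them against human annotations or
against each other: sample-by-sample chance-corrected agreement,
leave-one-subject-out threshold fitting, event matching, and boundary-bias
metrics. A seeded simulator generates head-rotation recordings with exact
ground truth, so every stage of the pipeline can be validated end to end.

## Kinematic quantities

A recording is an `OrientationTrace`: strictly increasing timestamps with
one unit quaternion per sample, in the engine convention where Y is the up
(yaw) axis, X the left/right (pitch) axis and Z the forward (roll) axis.
HMD streams carry timestamp jitter, so traces are first resampled onto a
uniform grid (90 Hz by default, the common display refresh) by spherical
linear interpolation, which is exact for constant-rate rotations.

From a uniform trace we derive:

* **Angular speed** (deg/s): the geodesic angle between consecutive
  orientations divided by the sample interval. Each sample describes the
  step *ending* at it; the first sample copies the second so all series
  share the trace's length. Quaternion double cover is removed by sign
  alignment before differencing, and the angle itself is computed as
  `4 * atan2(|q1 - q2|, |q1 + q2|)`, which remains accurate for the
  micro-rotations (≪ 0.01 deg) that dominate rest periods.
* **Per-axis angular velocity** (deg/s): central finite differences of
  unwrapped engine Euler angles — the axis-wise rotation rates an engine
  reports, which is what the baseline-threshold classifier was designed
  around. Samples with |pitch| > 89 deg are flagged in a gimbal-quality
  mask rather than rejected. Body-frame angular velocity from quaternion
  differentiation (`method = "body"`) is available for users who prefer a
  coordinate-free rate; the Euler-rate default matches how engine rotation
  channels are logged.
* **Angular acceleration** (deg/s²): central difference of the speed
  series, one-sided at the endpoints.
* **Head-angle magnitude** (deg): the angle between the head's forward
  vector and the world forward vector, in [0, 180]; invariant to roll.

Two smoothing primitives serve the classifiers: Savitzky–Golay
least-squares polynomial smoothing (reproduces polynomials up to its order
exactly, including at series edges) and a zero-phase low-pass filter
(order-2 Butterworth run forward and backward) whose zero-phase property
matters because one classifier segments on the *zero crossings* of
filtered acceleration — a causal filter would shift them in time.

Durations configured in milliseconds convert to samples as
`max(1, round(ms * rate / 1000))`, with Savitzky–Golay windows forced odd
by rounding up.

## The five classifiers

**BMAT (baseline movement adaptive threshold).** An adaptation of the
elliptic velocity threshold used for microsaccade detection. The per-axis
angular velocities recorded in the 500 ms stationary window before each
trial start parameterize a 3-D ellipsoid centred at the baseline mean with
semi-axes $n\sigma_a$; a sample is moving when

$$\sum_{a\in\{x,y,z\}}\left(\frac{v_a-\mu_a}{n\,\sigma_a}\right)^2 > 1.$$

$n$ is the classifier's single free parameter, fitted over a 0.2–4.0 grid.
Axis SDs are floored at $10^{-6}$ deg/s; a baseline with zero variance on
all axes is rejected outright, since no finite ellipse exists. The
median-based robust noise estimator from the microsaccade literature is
available behind `robust = TRUE` but is not the default, which uses the
plain mean/SD the ellipse definition names. BMAT emits per-sample labels;
no minimum event duration is imposed.

**SVT (smoothed velocity threshold).** Angular speed is Savitzky–Golay
smoothed (122 ms window, order 3 by default — about 11 samples at 90 Hz);
every local maximum of the smoothed speed above the speed threshold seeds
an event, and the algorithm walks backward/forward from the peak to the
nearest acceleration zero crossing. Three numerical choices matter here:

1. The walk's acceleration is the *backward* difference of the smoothed
   speed, matching the speed series' own step-ending convention, so that
   boundary zero crossings align with the speed support instead of
   lagging it by half a stencil.
2. "Zero" means a sign change or |a| below a plateau tolerance (1 deg/s²
   by default), but a zero crossing only terminates the walk once the
   smoothed speed is back below the threshold. Without this gate the sign
   flip at the speed peak itself — or the near-zero acceleration along a
   constant-velocity pursuit plateau — truncates events at the peak.
3. The offset test looks one sample ahead (`a[j+1]`), so the first
   stationary sample terminates the walk and becomes the exclusive bound
   of the half-open event window.

Events that overlap or share a boundary merge. The smoothing window
trades noise robustness against temporal smear: every boundary moves
outward by roughly half the window, which is visible as an onset/offset
bias of a few samples. On noise-free input a short window (55 ms) is the
appropriate setting; the 122 ms default is sized for jittery recordings.

**Chen & Walton.** A sliding-window percentage rule from the macaque
head-movement literature. A 100 ms onset window qualifies when at least
⌈0.72·w⌉ of its samples exceed the speed threshold (6 deg/s default) *and*
it contains no run of 3+ consecutive below-threshold samples; onset is the
first above-threshold sample of the first qualifying window. The scan then
switches to a 22 ms offset window requiring ⌈0.72·w⌉ samples below
threshold; offset is its first below-threshold sample, and the modes
alternate. The consecutive-below rule is evaluated *within* the candidate
window — the published description is ambiguous between that and a
running count since onset; the within-window reading keeps every window's
verdict independent of scan history, which is also what makes the
brute-force window-by-window oracle in the test suite equivalent to the
streaming scan. Counts use the ⌈·⌉ convention so "at least 72%" is exact
for any window length.

**DIZCO (differential zero-crossing observation).** The only direction-
aware classifier. The yaw (left/right) and pitch (up/down) rotation rates
are differentiated, low-passed below 10 Hz with the zero-phase filter, and
the recording is segmented at zero crossings of either filtered
acceleration. Each segment gets a per-channel state: resting (0) when the
segment's mean |filtered acceleration| is below the magnitude threshold,
otherwise the sign of the channel's rotation slope — its mean filtered
velocity. Using the velocity sign (not the acceleration sign) is what
lets a ballistic movement's accelerating and decelerating halves share a
label and fuse into one directed event; coding by acceleration sign
splits every movement into two opposite-direction halves. The state pair
maps onto eight compass directions (horizontal + = E, vertical + = N).
One- or two-sample sub-threshold slivers that sit exactly at a movement's
interior zero crossing are bridged (up to 50 ms) when flanked by
identical directions. The magnitude threshold was set by trial and error
in the original method; the package replaces that with a reproducible
default — the 95th percentile of filtered acceleration magnitude during
the pre-trial rest windows — overridable in `dizco_config()`. Known
limitation: sustained constant-velocity movement has near-zero
acceleration, so DIZCO's activity gate classifies the middle of long
pursuit plateaus as rest; its agreement scores on pursuit-style data are
accordingly poor, which is inherent to acceleration-gated segmentation
rather than to this implementation.

**Decision tree.** A supervised per-sample labeler: Gini-impurity splits
on two features — smoothed angular speed and head-angle magnitude at the
current time step — with depth capped at 10. Cross-validation folds are
*contiguous blocks*, not random shuffles: head-tracking samples are
strongly autocorrelated, and shuffled folds would leak nearly identical
neighbouring samples between training and validation. Predicted label
runs are converted to events, and events shorter than half the raters'
mean coded interval are discarded (strict inequality at the cutoff, so
events exactly at the boundary survive).

## Agreement, matching and bias

Agreement between two labelers is Cohen's kappa on per-sample
moving/stationary labels, $K = (P_o - P_e)/(1 - P_e)$, with $P_e$ from the
marginal label frequencies. Scoring respects a mask; by default the
fitting routines score only samples between a trial's start and the
response, the span human raters actually annotate. When both labelers are
constant and identical $P_e = 1$ and kappa is reported as undefined
rather than coerced to a number.

Ground truth for event-level comparison is the per-sample OR of the
raters' labels; maximal runs of the union form ground-truth events. A
ground-truth event matches a classifier event when its midpoint
((onset+offset)/2, in continuous time, not snapped to the grid) falls in
the classifier event's half-open window; any classifier event containing
two or more midpoints is removed with all its pairings, so the result is
strictly one-to-one. Bias is the human value minus the classifier value
(positive onset bias: raters placed the start later than the algorithm),
reported in ms with across-pair standard errors. Amplitude for human
events — raters mark times only — is derived from the orientation trace
between the rated times, as the geodesic angle between the boundary
orientations (net displacement; path length is available as an optional
column, and the two differ whenever a movement doubles back).

The main sequence is the Pearson correlation between event amplitude and
peak velocity, the stereotyped relation borrowed from saccade research.

## Threshold fitting

`grid_search()` evaluates a threshold grid by running the classifier per
subject, scoring kappa against each rater within trial windows, averaging
within subject and then across subjects. `fit_loo()` wraps it in
leave-one-subject-out selection: for each held-out subject the threshold
maximizing the remaining subjects' mean kappa is chosen — ties break
toward the *smallest* threshold, favouring sensitivity — and evaluated on
the held-out subject. Selection is deterministic given data and grid.
Default grids: BMAT multiplier 0.2–4.0 by 0.1; SVT 2–40 deg/s by 0.5 and
Chen & Walton 1–15 deg/s by 0.25 (speed grids sized to bracket both
ballistic peaks and pursuit-speed movements). Fits are run per condition,
since ballistic and pursuit movements favour very different thresholds.

## The simulator

`simulate_trace()` emulates a target-orienting paradigm: per trial, a
500 ms pre-trial rest (the BMAT baseline window), trial start, 500 ms
fixation, target onset at an eccentricity drawn from {10, 20, 30, 40,
50} deg in one of eight compass directions, a reaction latency
(150–200 ms), one orienting head movement toward the target, a hold
period, the response, and a ballistic re-centering movement. The head
covers 60% of target eccentricity (heads under-rotate relative to gaze;
the gain is a free parameter, not an empirical claim). Ballistic
movements follow a raised-cosine speed profile with peak velocity =
5 (deg/s)/deg × amplitude, perturbed by log-normal noise (SD 0.1 on the
log scale), which builds a main-sequence relation into the ground truth;
pursuit movements track at 20 deg/s with 150 ms cosine ramps. Orientation
jitter is band-limited Gaussian noise (0.02 deg SD per axis, low-passed
at 6 Hz) — roughly the optical-tracking noise floor of consumer HMDs.
Trial segments are snapped to the global sample grid so the concatenated
trace is exactly uniform.

Simulated raters reproduce the ground-truth events with Gaussian boundary
jitter (12 ms SD by default), a 2% miss probability, and optional
deterministic boundary shifts used to validate the bias pipeline.
Optional extras: a small corrective movement after the main one
(exercises one-to-many event matching), and sub-threshold "postural
wobble" during holds — out-and-back adjustments whose peak speeds are
drawn up to a ceiling (10 deg/s by default). Raters do not label wobble,
so the wobble ceiling acts as the recording's *effective velocity
boundary* between unlabeled drift and labeled movements; threshold
fitting on such recordings should recover it, which is exactly what the
recovery tests assert. All randomness flows from one integer seed through
per-trial substreams, so identical seeds give bit-identical recordings.

What the simulator does *not* capture: vestibulo-ocular and eye-head
coupling, torso motion, tracker dropouts, drift nonstationarity, and the
idiosyncratic criteria of real human raters (whose inter-rater kappa in
comparable studies is far below the jitter-only model's). Passing
recovery tests therefore demonstrates that the implementations are
faithful to their definitions and can recover known structure — not that
any particular threshold will transfer to real recordings.

## Problem sizes and test design

The validation suite and the study script run at desk scale by choice:
six simulated subjects, twelve trials per condition, 90 Hz. Recovery
checks use seeded simulations; cross-checks pit each implementation
against an independent oracle (a brute-force contingency table for kappa,
a literal window-by-window re-scan for Chen & Walton, an independently
implemented recursive-partitioning fit for the decision tree) rather than
re-deriving expected values from the code under test.

`scripts/acceptance.R` reruns the full study — simulation, rater
agreement, per-condition leave-one-out fits for the three thresholding
classifiers, DIZCO and decision-tree scoring, main-sequence correlations,
and SVT boundary biases — from a single seed and writes every quantity as
JSON.

## Known limitations

* Event boundaries are resolved to one sample (11.1 ms at 90 Hz);
  sub-sample boundary interpolation is not attempted.
* BMAT has no defence against slow postural drift faster than its
  baseline noise: drift above a few baseline SDs is labeled movement at
  any multiplier in the fitted range.
* DIZCO's rest gate suppresses sustained constant-velocity segments, as
  discussed above.
* Euler-rate per-axis velocities degrade near gimbal lock; the quality
  mask flags but does not repair those samples.
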