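---
title: "Linear and nonlinear visual feature learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear and nonlinear visual feature learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A visual category rule can be *first order* — some single pixel (or local
feature) carries information about the category — or *higher order*, where
only a combination of features is informative. The classic second-order case
is XOR: each input alone is uninformative, the agreement of two inputs
decides the class. `crosslearn` implements a complete computational pipeline
around a minimal stimulus family that dissociates the two cases:
cross-shaped figures with a central vertical arm and one horizontal arm near
the top or bottom on each side. Two mappings over the same four stimuli
define:

* the **linear task** — targets are the stimuli whose *right* arm sits near
  the top. A single local cue (one image region) solves it.
* the **nonlinear task** — targets are the mirror-symmetric stimuli (left
  arm height equal to right arm height). This is an XOR over the two arm
  heights: no fixed image region is informative, and in pixel space the two
  class means are *identical* (the class-mean collision), so no linear
  readout can separate the classes.

The package provides: stimulus construction and rendering; pixel- and
V1-model-based dissimilarity; a perceptron readout that certifies the
linear/nonlinear distinction; a synthetic behavioral simulator emulating
rodent touchscreen sessions and human trial streams; backward learning-curve
construction with constrained logistic-growth fitting; and template-based
strategy analysis.

# Stimuli

`stim_geometry()` fixes the physical layout: 61.92 degrees wide, 69.98
degrees tall, central arm 17.06 degrees wide. Horizontal arm proportions are
not uniquely determined by the published figure, so the package declares
them: arms are as thick as the central arm is wide, run from the central
arm's edge to the lateral canvas edge, and sit flush with the top/bottom
edge. All of these are parameters.

Rasterization is symmetric about both canvas midlines (regions are defined
by a center and a rounded half-width), so a configuration with equal left
and right occupancy renders to an exactly mirror-symmetric image — the
symmetry-related invariants are machine-precision facts, not approximations.
The coordinate convention is row-major with the origin at the top-left; row
1 is the top of the stimulus. Default resolution is 2 px/degree (124 x 140
px), a compromise that keeps the V1 encodes fast while leaving the arm
regions much larger than any filter; distances change by less than 0.02
between 1 and 4 px/degree.

The pixel dissimilarity between two binary images is the summed squared
pixel difference divided by the pixel count — the squared Euclidean distance
normalized by the maximal difference in an n-dimensional unit hypercube, so
it lies in [0, 1]. On the four base stimuli this already shows the
signature pattern: for the nonlinear task the two targets differ in all four
arm slots while a target and a distractor differ in two, so *within*-class
dissimilarity exceeds *between*-class dissimilarity; for the linear task the
inequality reverses.

The single-arm manipulation operator (`enumerate_manipulations()`) removes
an existing horizontal arm or fills an empty slot, never touching the
central arm: this is the only editing rule that reproduces the published
design counts — 6 unique manipulated positives, 6 negatives, 36 pairwise
combinations, 4 removed as identical, 32 retained
(`build_manipulated_pairs()`).

# The V1 encoding model

`v1_encode()` applies, in fixed order: local divisive normalization of the
input; convolution with a Gabor filter bank; output nonlinearities
(thresholding and response saturation); and local divisive normalization of
the output, followed by spatial subsampling. Divisive normalization divides
each value by a stabilizer plus the local L2 norm of its 3 x 3 neighborhood;
because the pooled norm dominates the center value, outputs are bounded by
1, and a constant input produces a constant (zero-variance) code.

The published description of this model family does not fix parameter
values, so the defaults are declared design choices, all exposed in
`filterbank_spec()` and `v1_params()`:

* **16 orientations** uniformly spanning 0-180 degrees. The grid is closed
  under the reflection `theta -> 180 - theta`, so the bank treats the two
  halves of a mirror-symmetric stimulus identically.
* **2 phases, 0 and 180 degrees** (an ON/OFF cosine pair). Cosine phases are
  exactly closed under horizontal reflection; sine phases are not, and would
  break the mirror-equivariance property after rectification.
* **6 spatial frequencies**, log-spaced over 0.1-0.6 cycles/degree.
* **Filter size 31 px** at 2 px/degree (15.5 degrees). This is deliberately
  *narrower than the central arm* (17.06 degrees = 34 px): together with the
  two 3 x 3 normalization neighborhoods, no model unit ever pools pixels
  from both lateral arm regions. Every response is therefore a function of
  the left arm alone, the right arm alone, or neither — which makes the
  class-mean collision of the nonlinear task hold *exactly* in V1 feature
  space, not just in pixel space. A larger filter could straddle the central
  arm and create AND-like conjunction units, silently weakening the
  non-separability argument the model is meant to demonstrate.
* Convolution keeps the **valid region only** (no padding), so border
  artifacts never enter the code; response maps are subsampled with stride
  4 by default (the qualitative results are stride-invariant over strides
  2, 4 and 8, which the acceptance suite checks).

The model dissimilarity between two stimuli is `1 - cor(r_i, r_j)` over
their response vectors, in [0, 2]; a zero-variance response vector makes the
correlation undefined and is reported as an error rather than silently
mapped to a value.

# The perceptron readout

`perceptron_train()` is the classic algorithm: unit learning rate, bias
term, weights initialized at zero, misclassified examples added to or
subtracted from the weights. The tie at exactly zero activation predicts the
distractor, so the all-zero initial state makes errors and learns. Training
stops early on the first zero-update epoch; per-epoch accuracy over the full
dataset is recorded (20-epoch budget by default). On separable data the
algorithm converges in finite time; on the nonlinear task it cannot,
because any separating hyperplane would need the common class mean strictly
on both sides. `separability_certificate()` returns
`"non-separable-by-mean-collision"` when the class means are exactly equal,
`"separable"` on perceptron convergence, and `"unknown"` otherwise — the
honest third state, since non-convergence within a finite budget proves
nothing by itself.

# The behavioral simulator

The simulator is the package's synthetic-data generator: it emulates the
data-generating process of the two training protocols so that every
downstream stage is testable without the (non-public) behavioral data.

**Protocols.** `protocol_rat()`: daily sessions of 100 non-correction
trials (the published protocol caps sessions at 60 minutes, not a trial
count; 100 is a realistic default), correction trials after every error,
criterion = accuracy above 0.80 in each of two consecutive sessions, session
cap 40. `protocol_human()`: a continuous stream of 12-trial blocks — each
pair 3 times, target on the left exactly 6 times, pair order and side
randomized independently — with criterion = running mean of the last 20
trials above 0.80.

**Correction trials** re-present the same trial after an error. Simulated
subjects answer them by lose-shift (switching away from the just-punished
side), which ends every correction run after one trial; a deterministic
wrong policy would otherwise loop forever. Correction trials are flagged in
the log and excluded from every performance computation. Learning updates
are applied on regular trials only, so each scheduled trial contributes one
feedback sample.

**Strategies.** `strategy_random()` and `strategy_oracle()` bracket the
performance range. `strategy_pixel_similarity()` is an exemplar-averaging
similarity agent. The central agent, `strategy_linear_template()`, holds a
weight image `w` and chooses the side whose image scores higher under `w`.
Its learning rule is an exponentially weighted running average of the
per-trial feedback signal (target image minus distractor image), corrupted
by Gaussian *encoding noise*; its choice adds Gaussian *decision noise* to
the normalized template score (a probit choice rule) plus a small lapse
rate. Three properties motivate this form:

1. the template converges to the class-mean difference image — the ideal
   linear template for the linear task, and exactly zero in expectation for
   the nonlinear task (class-mean collision), so the agent provably stays at
   chance there;
2. encoding noise makes a single feedback sample unreliable, so reliable
   performance emerges only through averaging — acquisition spreads over
   many sessions instead of completing within the first one;
3. after staged training on a single pair, the accumulated template
   transfers: it immediately helps a new pair consistent with the linear
   rule and *hurts* a new pair whose target conflicts with it, reproducing
   the old-pair/new-pair dissociation as a simulation property.

The defaults (learning rate 5e-4, encoding noise 60, decision noise 0.25,
lapse 0.05) were calibrated once so that simulated rats acquire the linear
task on the reported scale — roughly 15-25 sessions, no subject faster than
the 9-session backward window — and were not revisited afterwards. Human
cohorts in the default pipeline use lapsing oracle agents: humans solved
both tasks, and modeling human concept discovery is outside the package's
scope.

**What the generator does not emulate:** reaction times, side biases,
motivational drift, shaping, or session-to-session forgetting. Passing
tests on simulated cohorts therefore validate the *pipeline* (alignment,
fitting, intervals, correlations), and the qualitative dissociations; they
are not evidence about real rats beyond the model assumptions above.

# Backward learning curves and growth-curve fitting

`backward_curve()` aligns every subject at the point where the criterion
was reached and averages performance backwards: the criterion trial plus the
19 preceding trials for humans (window 20, unit = trial), the criterion
session plus the 8 preceding sessions for rats (window 9, unit = session).
Every point averages the same number of subjects. Subjects that never
reached criterion cannot be aligned; they are excluded with a warning and a
reported count, or the whole group can be aligned at its final session
(`align = "end"`) — the route a chance-level group takes toward its linear
fit.

Positions are indexed 1 through `window`, with the criterion point at
`x = window`. (The published parameter values — midpoint starts of 10 and 5,
midpoint upper bounds of 20 and 10, and fitted midpoints like 6.65 on a
9-session window — are only consistent with positive position indices, so
that is the convention implemented.)

The growth model is `y = b + b * L / (1 + exp(-k (x - x0)))` with the
baseline constant `b = 0.55` as printed — deliberately kept at the printed
value rather than silently corrected to chance 0.5; `baseline = 0.5` is one
argument away. The printed bound table transposes the bounds on `k`
(lower 1, upper -1); the package treats this as typographic and uses
`k` in [-1, 1]. Fitting is bounded nonlinear least squares:
`stats::nls(algorithm = "port")` first, refined by (and falling back to)
bounded quasi-Newton on the SSE, which handles the zero-residual noiseless
case where Gauss-Newton has no gradient signal. Non-convergence is always
reported via a flag, never silently. Noiseless curves generated from
published-scale parameter triples are recovered to below 1e-3 with SSE below
1e-10, and the optimum is stable under perturbed start values.

Whether the published fits used subject-averaged curves or pooled trials is
not stated; the package fits subject-averaged curves (matching how the
curves themselves are displayed) and notes this as an assumption.

**Parameter recovery study.** The validation suite draws 100 parameter
triples spanning L in [0.3, 0.9], k in [0.1, 0.8], x0 in [2, 15], simulates
cohorts of 30 subjects whose curve points are 60-trial session accuracies
(20 points per subject), refits, and requires the median absolute error to
stay within 10% of each parameter's range (observed: about 0.006, 0.02 and
0.13 for L, k, x0). The session-level design matters: with single Bernoulli
trials as curve points, the steepness `k` is genuinely unidentifiable at
this noise level — fits routinely reach *lower* SSE than the generating
parameters — so trial-level recovery at that tolerance is impossible for
any least-squares fitter, not a defect of this one.

# Strategy analysis

`template_model()` defines the full-canvas, upper-field and lower-field
region models; the top/bottom boundary defaults to the horizontal midline
and is a parameter. `template_prediction()` implements the chance rule: a
model predicts 0.5 for a pair whose two stimuli are identical within its
region, 1.0 otherwise; graded mode instead maps the normalized in-region
pixel difference to [0.5, 1], which is the recommended mode for the full
model (in binary mode the full model predicts 1.0 for every non-identical
pair and has zero variance — flagged, not errored).

`per_pair_performance()` counts successes per pair over a trailing session
window, excluding correction trials, and attaches exact Clopper-Pearson
intervals (95% default). The chance-inclusion flag compares each pair's
accuracy against a central binomial band around 0.5. For *joint* statements
over all four pairs ("the animal is at chance on every pair"), the
acceptance suite uses a simultaneous band — Bonferroni-corrected exact
intervals at family-wise level 99% — because four independent pointwise 95%
checks would jointly fail about 17% of the time for a truly random agent,
by multiplicity alone.

`prediction_performance_correlation()` correlates template predictions with
observed per-pair accuracy (Pearson, two-sided t p-value, optional seeded
permutation p). One caveat the simulations make explicit: an ideal-template
agent performs *below* chance on pairs whose manipulation conflicts with
its template, while the binary model predicts 1.0 there; this attenuates the
matched-model correlation and drives the mismatched-model correlation
negative rather than to zero. The suite therefore asserts the ordering (the
matched model correlates best, positively) rather than any particular
magnitude.

`transfer_analysis()` reports old- and new-pair accuracy in the session the
second pair is introduced (with exact binomial intervals) and the
correlation of per-session accuracies across the remaining sessions of that
stage; constant series are flagged as zero-variance rather than given a
correlation.

# Pipeline and reproducibility

`run_all()` executes the whole analysis from one seeded `run_config()`:
stimulus manifest, both distance matrices with class summaries, the four
perceptron runs, simulated cohorts for both species and tasks, backward
curves with the model-selection report, the 32-pair template predictions,
the staged transfer analysis, and a machine-readable summary. Each random
stage derives its own sub-seed from the global seed and a fixed stage label,
so stages can be re-run in isolation; the same configuration and seed
produce byte-identical summaries. `validate_config()` checks every
structural invariant (block divisibility, side balance, filter-vs-canvas
size, bound ordering, cohort sizes) with actionable messages.

Problem sizes used by the test and acceptance suites — cohorts of 3
simulated rats, 40 random-agent replicates, 100 recovery cohorts, strides
2/4/8 at 2 px/degree — are the package's choices for a thorough but quick
validation run; all are parameters.

# Known limitations

* The V1 model's constants are declared, not fitted to neural data; the
  package demonstrates a separability property, not neural fidelity.
* The simulator's agents are intentionally minimal; they reproduce sign
  patterns and dissociations, not quantitative performance levels of real
  subjects.
* Published values that depend on the non-public behavioral data (mean
  trials/sessions to criterion, the template-correlation magnitudes, the
  transfer correlation value) are qualitative reference points only; the
  pipeline reproduces their sign patterns from simulation.
* The logistic model's parameters trade off strongly when a curve lacks
  clear baseline or asymptote stretches; fitted magnitudes near the bounds
  should be interpreted with the same caution the original analysis applied.
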