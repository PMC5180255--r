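# crosslearn

Computational pipeline for studying **linear versus nonlinear (XOR-like)
visual feature learning** with a minimal family of cross-shaped stimuli.

The package is built around a four-stimulus design: each stimulus is a
central vertical arm with a horizontal arm near the top or the bottom on
each side. Two category mappings over the same images dissociate feature
complexity in the sense of the *order of a problem*:

* **linear task** — target ⟺ the right arm sits near the top. A single
  image region is informative (a first-order problem: solvable by a fixed
  linear template over pixels).
* **nonlinear task** — target ⟺ left and right arm heights agree (the
  mirror-symmetric stimuli). This is XOR over the two arm heights: every
  single region is uninformative and the two class means are *identical*
  pixel-for-pixel, so no linear readout over pixels — or over any encoding
  whose units pool only one side — can solve it.

For a linear readout `sign(w·x + b)` the dissociation is exact: the
perceptron converges in finitely many epochs on the linear task and provably
cannot converge on the nonlinear task (class-mean collision). The package
verifies this on raw pixels and on a V1-like encoding (divisive input
normalization → Gabor filter bank → threshold/saturation → divisive output
normalization), computes pixel and model dissimilarity
(`d_pixel = Σ(p_i − p_j)² / n`, `d_model = 1 − corr(r_i, r_j)`), simulates
the two training protocols (rodent touchscreen sessions with correction
trials and an 80%-over-two-sessions criterion; human 12-trial pseudo-random
blocks with a 20-trial running-mean criterion), builds backward learning
curves aligned at the criterion point, fits the constrained logistic growth
model `y = b + bL / (1 + e^{−k(x − x0)})` (baseline `b = 0.55`) by bounded
nonlinear least squares, and analyzes decision strategies with region
template models, exact binomial intervals, and old/new-pair transfer.

## Worked example

```r
library(crosslearn)

# the manipulated-stimulus design used for strategy analysis
mp <- build_manipulated_pairs(task_mapping("linear"))
# -> 6 positives x 6 negatives = 36 pairs, 4 identical removed, 32 retained

# V1-model dissimilarity over the four base stimuli
images <- lapply(make_base_set(), render_stimulus, geometry = stim_geometry())
vm <- v1_response_matrix(images)
class_distance_from_matrix(task_mapping("linear"), vm$distances)
class_distance_from_matrix(task_mapping("nonlinear"), vm$distances)

# perceptron readout on the V1 responses
perceptron_train(task_dataset(task_mapping("linear"), "v1"), max_epochs = 20)
perceptron_train(task_dataset(task_mapping("nonlinear"), "v1"), max_epochs = 20)

# logistic growth fit on a noiseless 9-session backward curve
curve <- simulate_logistic_cohort(0.68, 0.68, 6.65, noiseless = TRUE, n_points = 9)
fit_logistic(curve, species = "rat")
```

Output:

```
model distance, linear task:    within = 0.272, between = 0.405
model distance, nonlinear task: within = 0.541, between = 0.270
<perceptron_fit> converged after 2 epoch(s); final accuracy 1.00
<perceptron_fit> did not converge after 20 epoch(s); final accuracy 0.50
<logistic_fit> L = 0.680, k = 0.680, x0 = 6.650 (baseline 0.55), SSE = 1.77e-21
```

Reading the numbers: under the nonlinear mapping the two *same-class*
(symmetric) stimuli are more dissimilar than a target/distractor pair —
within-class 0.541 exceeds between-class 0.270 — while the linear mapping
shows the reverse. Low-level similarity therefore actively opposes the
nonlinear grouping. The perceptron reaches 100% training accuracy on the
linear task in 2 epochs but stays at 50% across its 20-epoch budget on the
nonlinear task. The growth-curve fitter recovers the generating parameters
(L, k, x0) of a noiseless backward curve exactly (SSE ≈ 2e−21).

The full analysis — stimuli, distances, readouts, simulated rat and human
cohorts, backward curves and fits, template predictions, transfer analysis —
runs from one seeded configuration:

```r
res <- run_all(run_config(seed = 1), out_dir = "crosslearn_run")
res$summary
```

or from the shell via the thin wrapper
`Rscript inst/scripts/run_pipeline.R --seed 1 --out crosslearn_run`.

A methods vignette (`vignettes/crosslearn-methods.Rmd`) documents the
models, the simulator's assumptions and calibration, numerical choices, and
known limitations.

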