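---
title: "Methods: from reference-back behavior to directed band-specific networks"
author: "gatingnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from reference-back behavior to directed band-specific networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gatingnet)
```

This vignette is the package's own account of its models and the decisions
behind them: what each stage assumes, which parameters matter, how the
synthetic generators relate to real recordings, and where the numerical
corners are.

## The paradigm and the gating contrasts

In the reference-back task, red-framed (reference) trials require updating
the remembered letter and blue-framed (comparison) trials require only a
comparison against it. Crossing *Switching* (switch vs nonswitch relative to
the previous trial's frame color) with *Trial Type* gives four cells, and the
two gating processes are switch costs within a trial type:

* gate opening = switch-reference − nonswitch-reference,
* gate closing = switch-comparison − nonswitch-comparison.

`gatingContrast()` applies this to any per-cell measure (RT, error
percentage, or a fitted DDM parameter); it is linear in its inputs, which the
test suite checks directly.

## Behavioral statistics

`filterOutliers()` implements the two-stage ±k·SD rule (k = 2 by default):
trial-level trimming within subject first, then subject-level flags for mean
RT and per-condition trial counts against the group distribution. The order
(trials first, subjects second) is a package decision — the alternative
ordering is not distinguishable from published summaries — and both stages
are logged in the returned flags so a user can audit either. A subject whose
RTs are all identical has SD 0 and loses nothing (documented edge case);
`k = Inf` is the identity.

`rmAnova()` covers exactly the designs the paradigm needs: fully
within-subject factorials with 2-level factors. For such designs every
effect has one numerator degree of freedom and its F equals the squared
one-sample t of the per-subject contrast scores, which makes the
implementation exact rather than an approximation — the suite verifies
agreement with `stats::aov(... + Error(subj/(A*B)))` to 1e-8 on random data.
Sphericity corrections are unnecessary with 2-level factors, so none are
implemented. Effect sizes follow the conventions that reproduce published
(statistic, effect size) pairs: partial eta squared
`F·df_num/(F·df_num + df_err)` and the paired `d_z = t/√n`. The
`d_z` convention was fixed by checking printed (t, d) pairs for mutual
consistency (e.g. 6.93/√61 = 0.887).

## Drift-diffusion modeling

`simulateDDM()` is an Euler–Maruyama walk from `zr·a` with drift `v`, unit
diffusion, absorbed at 0 ("mismatch") or `a` ("match"); `rt = first-passage
time + t0`. The default step `dt = 1e-4` s keeps the discretization bias on
recovered parameters an order of magnitude below the recovery tolerances the
suite enforces (±0.05 on `a`, ±15 ms on `t0` at 500 trials/cell).

`wfptDensity()` evaluates the Wiener first-passage density through the
standard small-time and large-time series. For each evaluation point the
expansion needing fewer terms at the requested error bound is chosen; the
`precision` parameter (default 4) bounds the absolute truncation error of the
standardized density by `10^-precision`, mirroring the "precision 4.0"
semantics of the common ML fitting tools for this model. The suite verifies
the density against closed-form boundary probabilities by quadrature and
against the simulator by a KS-type comparison.

`fitDDMCell()`/`fitDDM()` maximize the summed log density of correct trials
with response-coded boundaries. Parameters are transformed
(`log a`, `v`, logit of `t0/min rt`) so the simplex search is unconstrained,
with bounds `a ∈ (0.3, 3)`, `|v| ≤ 5`, `t0 ∈ (0, min rt)` enforced by
penalty, and 5 seeded restarts around a moment-based initializer
(`P(match) = logistic(v·a)` for `zr = 0.5`). With `zr` fixed at 0.5 and
`p_match = 0.5`, restricting to correct trials selects upper- and
lower-boundary responses with equal probability, so the correct-trials
likelihood still identifies the generating parameters — this is why the
synthetic recovery studies work at all.

One consequence of response-coded boundaries and a single `v` per cell is
that generated accuracies sit near chance when `|v|` is small: the generator
reproduces the published *parameter structure* (condition-specific `a`, `v`,
`t0`), not published error rates; the two cannot both be matched under this
coding and we chose the parameters, which downstream stages consume.

### Default cohort parameters

The generator's condition cells solve the published marginal means and
switch costs: `a` = 0.950/0.910/0.905/0.815 and `t0` =
349.5/338.5/361.5/326.5 ms for switch-reference / nonswitch-reference /
switch-comparison / nonswitch-comparison (switch means 0.93 and 356 ms,
nonswitch 0.86 and 332 ms; closing costs exceed opening costs), with drift
0.13/0.01/0.05/0.01 (switch mean 0.09, nonswitch 0.01). The trial-type split
of `v` is underdetermined by marginal means; equal nonswitch drifts were
chosen once. Frame colors are i.i.d. with P(reference) = 0.5 — the task's
true transition structure is not published, so it is exposed as `pReference`
— and the first trial, having no predecessor, is unlabeled and dropped.

## Time–frequency analysis

`morletTFR()` reads "width 5.5" as cycles (Gaussian SD `5.5/(2πf)` s) and
"length 3" as the truncation of the Gaussian at 3 SDs per side — the common
toolbox convention; the terms are stated here because they are genuinely
ambiguous in the literature. Wavelets are amplitude-normalized, convolution
is FFT-based, and samples within half a wavelet of either epoch edge are
masked NA (the edge-effect blanks); a frequency whose wavelet exceeds the
whole epoch is fully masked with a warning. `dbBaseline()` computes
`10·log10(power/mean baseline power)` per channel × frequency over
−200…0 ms. Note the baseline *mean power* is the reference, so the mean of
the dB values over the baseline window is only ≈ 0 dB (Jensen's inequality);
the tests allow this bias. Band averages use inclusive edges (theta 4–7,
alpha 8–12, beta 13–30 Hz).

`clusterPermTest()` forms pointwise paired t maps, clusters suprathreshold
points (two-sided α = 0.05) that are adjacent in time or between neighboring
channels and share a sign, scores each cluster by its summed t, and builds
the null from the maximum absolute cluster sum under within-subject sign
flips — the correct exchangeability scheme for paired designs. Monte-Carlo
p-values are `(1 + #{null ≥ |stat|})/(nPerm + 1)`, bounded below by
`1/(nPerm + 1)`. Channel adjacency for synthetic layouts uses a distance
threshold of 1.5× the median nearest-neighbor distance. Calibration is
checked empirically: over 200 null simulations the family-wise false-positive
rate stays inside the binomial 95% interval around 0.05.

## Source reconstruction

`lcmvCommonFilter()` builds one common filter from the regularized sensor
covariance of all relevant conditions appended (default: average of
single-trial covariances; the covariance of the trial average is available
via `covMode = "average"` because the published description is ambiguous
between the two). Regularization is 5% of the mean sensor variance — a
common default where no value is published. The beamformer is scalar
(fixed-orientation), matching the synthetic leadfields; free-orientation
handling is out of scope. Unit gain holds algebraically, and the suite
checks it to 1e-10.

Voxel selection takes the top percentile by *absolute* contrast so that
suppression effects (alpha/beta power decreases) are selectable, with ties
broken by voxel index. DBSCAN uses `eps = 1.5×` grid spacing by default —
enough to connect face/edge neighbors on a regular grid but not
diagonal-distant voxels — and the published minimum of 2 voxels per cluster;
isolated voxels are noise and are discarded. Cluster signals are
baseline-subtracted per voxel (switch trial minus the mean nonswitch signal),
averaged over cluster voxels, and cropped to −500…1500 ms with a half-open
window, i.e. 512 samples at 256 Hz; the inclusive alternative would give
513, and the half-open convention was fixed once and documented.

## Effective connectivity

The model is an order-p nonlinear MVAR: each node's current sample is
predicted from the p past samples of all nodes by the sum of an explicit
linear map and a one-hidden-layer tanh network. Trials are embedded
independently (no regression row crosses a concatenation joint), nodes are
z-scored, and both paths are trained jointly by full-batch L-BFGS with
analytic gradients, 3 seeded restarts, the linear path initialized at the
OLS VAR solution and the hidden path at zero output weights. `hiddenUnits`
defaults to `2·M·p`; `p = 10` is the published order for real cluster
signals, while the synthetic studies use the generating orders.

Two decisions matter here:

* **Identifiability of the split.** A tanh layer is linear near the origin,
  so without care the hidden path absorbs linear structure and the
  linear/nonlinear decomposition is arbitrary. The package therefore (a)
  puts a small weight decay (default 0.01) on the hidden path only, biasing
  the fit toward the linear explanation, and (b) reassigns the hidden path's
  first-order term — its Jacobian at the origin — to the linear weights
  after training, leaving a nonlinear part with zero slope at the operating
  point. On purely linear data the nonlinear connectivity then collapses to
  ~0 while edge detection by the linear measure reaches AUC ≈ 1; on a
  square-coupled system the nonlinear measure recovers the direction in
  10/10 seeded runs. Both behaviors are enforced by the acceptance tests.
* **Connectivity definitions.** The published method defers the extraction
  formulas to its methodological source, so the package fixes them
  explicitly: `lC(i→j)` = mean over lags of |linear weight (j ← i)|, and
  `NC(i→j)` = mean over observed samples and lags of
  |∂ f_nonlin,j / ∂ x_i(n−k)| along the trajectory. Sensitivity-based
  attribution is the canonical reading of "information embedded within the
  nonlinear part", and both definitions reduce correctly in the linear and
  zero-coupling limits — which is how they are validated, rather than by
  matching any external implementation numerically.

Normalization divides a subject's full band × condition set by its maximum
**non-self** value, separately for each measure. The non-self reference is a
package decision: self (diagonal) autoregressive weights dominate any
cross-connection, and normalized non-self averages on the published scale
(≈ 0.45–0.68) are only attainable with a non-self reference. The diagonal is
reported but excluded from the [0, 1] guarantee and from non-self averages.
Normalization is monotone and idempotent, and `selectOrder()` provides
AIC/BIC order diagnostics on the linear backbone (AIC never selects below
BIC).

## Brain–behavior regression

`fitPredictCV()` regresses one DDM parameter on per-subject connectivity
summaries with a one-hidden-layer network (`nnet`, 8 hidden units, weight
decay 0.05 by default — with cohort-sized n, regularization does the work
that early stopping would otherwise do). The goodness of fit is the
normalized error: mean 10-fold CV squared error divided by the mean absolute
target, which removes the target's scale (scaling y by c scales the measure
by c — tested). CIs are t-intervals over fold errors; two conditions differ
when their 95% CIs are disjoint, and this rule agrees with a permutation
test on fold errors in ≥ 90% of synthetic comparisons. Models are fit per
target and per band × condition, matching how per-parameter prediction
errors are reported in this literature.

## The synthetic pipeline and what passing it shows

`runPipeline()` wires the stages together on synthetic data in which each
subject's coupling gain drives both the directed source coupling *and* the
boundary separation, while drift rate is independent noise — so the final
regression stage should, and does, predict `a` far better than `v`. Switch
trials additionally carry an event-related post-onset amplitude increase;
without one, a stationary coupling difference would be cancelled by decibel
baseline normalization and the sensor-level permutation test would be blind
to it. Problem sizes in the default config (8 subjects, 60 trials/cell,
128 Hz, −1…1 s epochs, 64 voxels, 24 sensors, order-2 connectivity) were
chosen so a full run completes in well under a minute while every stage
still has measurable signal; the acceptance studies use larger sizes
(T = 4000 for connectivity, 500 trials/cell for DDM recovery).

The generators emulate: condition-specific DDM behavior; stationary
band-limited coupled sources with exact nMVAR dynamics (narrowband
innovations rather than post-hoc filtering, so the recursion stays exact);
distance-decaying leadfields on regular grids; white sensor noise. They do
not emulate: 1/f background spectra, artifacts (blinks, muscle), volume
conduction from realistic head geometry, nonstationary coupling, or
inter-regional delays beyond integer lags. Passing the suite therefore
demonstrates that each stage implements its model correctly and that the
chain is consistent end to end — not that the pipeline's statistical power
or specificity on real recordings matches the synthetic figures.

## Numerical corners

* Seeds: one master seed; every stage and substream derives its own seed by
  a documented integer recurrence, so stages are independently reproducible
  and re-runs are byte-identical.
* Overflow guard: the nMVAR generator aborts with a diagnostic when any
  |x| exceeds 1e6 (divergent nonlinear feedback).
* FIR band-pass: Hamming-windowed sinc, order ≈ 3.3·fs/transition-width
  (transition width max(1 Hz, 25% of the lower edge)), applied as a single
  centred convolution of the symmetric kernel — zero phase with the
  single-pass magnitude response; short signals get the largest admissible
  kernel. Filtering twice squares the response (LTI cascade), which the
  tests use as a check.
* Degenerate inputs: zero-variance paired differences give the documented
  t = 0 / ±Inf results; all-zero connectivity sets refuse normalization;
  empty TFR bands, mismatched grids and out-of-range cluster voxels raise
  named errors.
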