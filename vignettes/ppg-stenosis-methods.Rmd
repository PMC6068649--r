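---
title: "Methods: PPG pulse-slope analysis and MLP stenosis grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPG pulse-slope analysis and MLP stenosis grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgstenosis)
```

This vignette documents the modelling choices behind `ppgstenosis`: what
each stage assumes, which parameters matter and why their defaults are what
they are, what the synthetic generator does and does not emulate, and the
numerical conventions adopted where the underlying method leaves room.

## The pipeline

A recording is a single-channel PPG waveform sampled at 1 kHz, tagged with
hand (the treated "HD hand" versus the untreated one), treatment phase
(before/after a hemodialysis session) and subject. The chain is

1. **Conditioning** — robust local-regression smoothing, then OLS
   detrending.
2. **Feature generation** — peak/valley landmarks, the first 12 complete
   beats, per-beat rising and falling slopes, min–max rescaling, and
   mean/variance summaries per recording.
3. **Feature selection** — paired t-test of before versus after treatment
   per slope feature at α = 0.05.
4. **Grading** — degree of stenosis from vessel diameters, three-class
   partition, and a 4–35–3 logistic-sigmoid MLP trained by
   Levenberg–Marquardt (LM), scaled conjugate gradient (SCG) or resilient
   backpropagation (RProp), evaluated by repeated stratified 5-fold
   cross-validation with micro-aggregated metrics.

## Signal conditioning

`smooth_ppg()` implements the classical robust LOESS recipe: at every
sample a polynomial of degree 2 (configurable to 1) is fitted by weighted
least squares over a centred window covering a fraction `span` (default
0.01) of the record, with tricube distance weights; `robust_iterations`
(default 5) rounds of bisquare reweighting at six times the median absolute
residual suppress outliers. Because the sample grid is regular, every
window shares the same offset abscissa, so the normal-equation sums are
computed by convolution and each per-point system is solved in closed form
— O(n·window) rather than O(n·window²). Conventions chosen where the
recipe is silent:

* **Edges**: windows are truncated at the record boundaries (no padding,
  no nearest-neighbour widening). The first/last half-window is therefore
  fitted from fewer points; tests only assert landmark properties away
  from the edges.
* **Degenerate scale**: if the median absolute residual is zero the robust
  iteration stops (the fit already interpolates).
* A plain centred moving average over the same window is available
  (`method = "moving_average"`) for comparison; the robust local
  regression is the default because its parameters (1% span, second-degree
  polynomial) are the specified conditioning for this signal class.

`detrend_ppg()` subtracts the OLS line, removing constant offset and linear
drift exactly; outlier suppression is the robust smoother's job. Slopes are
finite differences of landmark values, so they are invariant to the removed
offset and, to first order, to the removed drift.

## Beat landmarks and slope features

Peaks are local maxima filtered by topographic prominence (default 10% of
the signal IQR) and a minimum inter-peak distance (default 0.4 s, i.e. at
most 150 beats/min); valleys are the minima between consecutive accepted
peaks and before/after the first/last peak. Each accepted peak is then
re-anchored to the maximum between its flanking valleys, which guarantees
the strict valley–peak–valley alternation the slope definitions assume. A
beat is a (valley, peak, valley) triplet; consecutive beats share valleys.
The analysis window is the first 12 complete beats (`select_beats()`), and
a shortfall is an error that names the available count.

The rising slope `(V_p − V_n)/(T_pn − T_n)` is positive by construction for
a valid beat. The falling slope is algebraically negative on a descending
limb; the package reports its magnitude — matching how such tables are
conventionally printed — and exposes the signed value (`fs_signed`) for
anyone who needs the orientation. Non-positive slopes in selected beats
raise an error, since they indicate landmark mis-ordering rather than a
physiological condition.

**Rescaling scope.** Min–max rescaling to [0, 1] can be applied at two
points. Rescaling the *per-beat* values within each recording before
summarising erases the absolute slope level — every recording then spans
[0, 1] regardless of how steep its pulses are — and the absolute level is
precisely what carries the stenosis signal. The pipeline therefore
summarises raw slopes and rescales the four *summary features* columnwise
across the cohort before they enter the network (sigmoid networks want
bounded inputs). The per-recording beat-level rescale remains available
(`rescale_beats = TRUE`) for sensitivity analyses.

## Feature selection

`slope_t_test()` defaults to the two-sided *paired* Student t-test on the
per-subject after-minus-before differences. The unpaired Welch statistic
`(x̄₁ − x̄₂)/√(S₁²/n₁ + S₂²/n₂)` is also implemented (`variant = "welch"`),
because before/after comparisons are sometimes written in that form; for
the bundled reference cohort only the paired variant reproduces the
tabulated p-values, which is why it is the default. Rejection uses strict
inequality at α; a p-value exactly at α is not rejected. If no feature is
significant the pipeline warns and falls back to all features rather than
leaving the classifier without inputs. No multiple-testing correction is
applied across the two features — deliberately, to match the reference
analysis; with only two tests the issue is noted rather than corrected.

## Degree of stenosis and classes

`DOS% = (1 − d²/D²) × 100` needs only the diameter ratio, so any single
consistent unit works. The published three-class partition is ambiguous at
exactly 30% and 50%; the package uses half-open intervals [0, 30],
(30, 50], (50, 100], a deterministic convention that no reference patient
actually sits on. When a patient table carries a printed DOS column,
`label_patients()` recomputes the DOS from the diameters and *flags* rows
that disagree beyond 0.005 (printed diameters are typically rounded after
the original DOS was computed); flagged rows are reported, never failed,
and their class assignment is unaffected.

## The MLP and its trainers

The network is a fully connected 4–35–3 perceptron with logistic sigmoids
at both layers. Bias terms are included even though the textbook neuron sum
`v = Σ x_i w_i` omits them: without biases the near-0/near-1 output
patterns the classifier must produce are unreachable at bounded inputs
(`use_bias = FALSE` restores the literal form). Initial weights *and*
biases are uniform in ±√(6/(fan_in+fan_out)), seeded; zero biases were
rejected because the resulting near-symmetric starting points noticeably
hurt LM's basin of attraction on small benchmark problems.

Residuals are `e = target − output`, the output delta is
`δ_k = y_k(1 − y_k)e_k`, and the batch gradient is assembled by
backpropagation; the per-sample, per-output error Jacobian `J = ∂e/∂w`
(rows sample-major) satisfies `∇(Σe²) = 2Jᵀe`, which a test asserts to
1e-10 against the direct backprop gradient, alongside a central
finite-difference check.

All trainers are full batch (LM requires it; the others follow for
comparability) and share one stopping contract: MSE ≤ `error_goal`
(default 10⁻³), `max_epochs` (default 1000), or a vanishing gradient.
Algorithm constants, exposed in `train_config()`:

* **LM**: μ₀ = 1e-3, ×10 on a rejected step, ÷10 on acceptance, stop at
  μ > 1e10. The damped system `(JᵀJ + μI)` is solved by Cholesky
  factorisation, never by forming the inverse the update formula is
  written with. Accepted steps strictly decrease the loss by construction.
* **SCG**: Møller's published constants σ = 5e-5, λ₀ = 5e-7; the curvature
  along a direction is estimated from a σ-scaled gradient perturbation,
  and λ is escalated whenever the estimate loses positive definiteness
  (non-finite escalation stops the run with a named reason).
* **RProp**: η⁺ = 1.2, η⁻ = 0.5, Δ₀ = 0.07, Δ ∈ [1e-6, 50], with weight
  backtracking on a gradient sign flip. The update magnitude is
  independent of the gradient magnitude by design.
* **GD reference**: the delta rule `Δw = η·y_j·δ_k` with η = 0.1 and
  momentum 0.95. These two parameters belong to this trainer only; none of
  the three main algorithms uses a learning rate or momentum.

Class decoding is arg-max over the three outputs with ties broken toward
the lower class index (`which.max` semantics) — with continuous sigmoid
outputs ties are measure-zero, but the convention is fixed and documented.

## Evaluation

Cross-validation is stratified: within each class the samples are shuffled
and dealt round-robin into k folds, so class proportions are preserved up
to integer rounding; with very small classes some folds lack a class, which
is benign because predictions are pooled across folds into a single
confusion matrix per repeat. Micro-aggregation over three classes forces
`FP = FN = N − TP` and `TN = N + TP`, hence `REC = PPV`,
`ACC = (1 + 2·REC)/3` and `SPE = (1 + REC)/2`; these identities are
asserted on every evaluation, and the geometric mean is recomputed from
the reported REC/SPE. Mean ± SD over repeats uses the n−1 denominator,
consistent with the variance summary. Per-fold (unpooled) metric averaging
is deliberately not the default, since single pooled matrices are what the
reported mean ± SD summaries describe. Wall-clock training and prediction
times are recorded for reporting only and are never part of any assertion.

## The synthetic generator

`generate_recording()` builds each beat from a half-cosine upstroke
(`rise_time` seconds to amplitude A) and an exponential-like decay back to
the foot. Because the slope features depend only on the landmark
*endpoints*, the true per-beat slopes have closed forms — RS = A/rise,
FS = A/(period − rise) — whatever the interior shape; that is the property
the template was chosen for. Ground truth is computed before offset,
sinusoidal drift and white noise are added, so raising `noise_sd` never
moves the truth; per-beat lognormal amplitude jitter *is* part of the
truth (it changes the beat, not the measurement).

`generate_cohort()` emulates a small dialysis cohort with known class
structure. Defaults, chosen once as a deliberately idealised but
physiologically plausible cohort:

* **Class structure** 5/4/2 patients (mild/moderate/severe), DOS drawn
  uniformly from [18, 26], [38, 46] and [72, 88]% — the same sample sizes
  as the reference cohort and DOS ranges that, like that cohort's actual
  values, leave clear margins around the 30% and 50% partition boundaries.
* **Slope–DOS coupling** RS_before = 5·(1 − 0.6·DOS/100) a.u./s with 2%
  lognormal between-subject variation: a severe access roughly halves the
  upstroke slope. The base slope of 5 a.u./s puts rise times at 0.2–0.4 s,
  the physiological range for a PPG systolic upstroke at the 0.8 s default
  period — and, importantly, wide enough that the 1%-span smoother (a
  ~120-sample window on the default record length) resolves the peak
  without flattening it.
* **Treatment effect** RS_after = RS_before·(1 + 0.2·DOS/100 + ε),
  ε ~ N(0, 0.02²): fluid removal steepens the upstroke, more so in
  stenosed access, which is the effect the paired t-test detects. Setting
  `after_effect = 0` yields an exact null cohort, used by the calibration
  test of the t-test's type-I error.
* **Beat-to-beat variability** lognormal amplitude jitter with SD
  0.02·(1 + 4·DOS/100): stenotic access pulses are less stable, which is
  what makes the *variance* summary features informative rather than pure
  chi-square sampling noise (with 12 beats a sample variance carries ~42%
  relative error, so only coupled variability is detectable at all).
* **Segments** Each patient contributes 2 recording segments, each its own
  before/after pair and evaluation vector (22 samples from 11 patients),
  mirroring reference analyses in which the evaluated sample count exceeds
  the patient count because several segments are taken per patient. The
  segment is the cross-validation unit; segments of one patient can land
  in different folds, an optimistic convention inherited from that design
  and worth remembering when reading the accuracies.
* **Artefacts** offset 0.5 a.u., 0.1 a.u. sinusoidal drift with a 12 s
  period, white noise SD 0.02 a.u. — visible but benign levels that the
  conditioning stage is expected to remove.

What the generator does **not** emulate: dicrotic notches and secondary
waves, heart-rate variability (the period is fixed within a recording),
motion artefacts, sensor saturation, arrhythmia, or any validated
hemodynamic link between DOS and pulse shape — the DOS→slope mapping is a
configurable stand-in, not a calibrated model. Passing tests on this
cohort therefore demonstrate that the pipeline recovers the structure the
generator encodes, not that real dual-PPG recordings are this separable.

## Problem sizes and numerical tolerances

The test suite runs the pipeline at deliberately small sizes chosen as
adequate for the properties under test: recordings of 13–15 beats at
1 kHz, cohorts of 6–22 evaluation vectors, 5-fold × 10-repeat
cross-validation, 10-seed trainer comparisons, and 200 replicates for the
type-I-error calibration (checked against the exact binomial 99% band
around α = 0.05). Exact algebraic properties (polynomial reproduction,
Jacobian consistency, aggregation identities) are asserted at 1e-8–1e-12;
properties of printed reference values are asserted at the precision those
values are printed with; stochastic properties are asserted as majorities
over seeds or as band membership, never as point equalities.

## Known limitations

* The smoother's fixed-width sample-domain window differs from
  nearest-neighbour LOESS variants near the record edges; landmark
  detection near the first and last half-window is correspondingly less
  reliable, and the beat selector's "first 12 beats" convention makes the
  pipeline insensitive to the trailing edge only.
* Variance summaries from 12 beats are intrinsically noisy; on real data
  they should be interpreted (and fed to classifiers) with that sampling
  error in mind.
* With ~20 training vectors and 283 network parameters the MLP
  interpolates its training folds; generalisation rests entirely on the
  class geometry of the features, and cross-validated accuracy has high
  run-to-run variance. The repeated-CV mean ± SD is the honest summary,
  and single-run accuracies should not be quoted.
* The untreated-hand channel is generated and carried through the data
  model but the bilateral (two-hand difference) analysis is out of scope.
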