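---
title: "Methods: hybrid Transformer-LSTM forecasting of CGM glucose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid Transformer-LSTM forecasting of CGM glucose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling choices behind `cgmforecast`: what is
assumed, what is calibrated, what is configurable, and what a passing test
suite does and does not establish.

## 1. Problem setting

Continuous glucose monitors report interstitial glucose roughly every 5
minutes, in mmol/L. Short-horizon forecasting (15–45 minutes ahead) gives a
patient or closed-loop controller time to react to an oncoming hypo- or
hyperglycemic excursion. We treat the task as direct multi-horizon
regression: for each prediction horizon PH a separate model maps the last
`L` samples to the scalar value PH minutes ahead. Direct (rather than
recursive) forecasting was chosen because the evaluation protocol reports
an independent MSE per horizon and the architectures end in a scalar head;
recursive rollout would couple the horizons and compound errors.

## 2. Data model and I/O

A `glucose_series` is one patient's strictly increasing timestamped trace,
glucose finite and positive, with an optional sparse capillary-calibration
column. The canonical CSV dialect is
`patient_id,timestamp,glucose_mmol_l,calibration_bg_mmol_l` with ISO-8601
UTC timestamps; a column-mapping dialect and an mg/dL converter (÷ 18.016)
handle device exports. Round-trips are lossless at the declared precision
(seconds, 4 decimal places of mmol/L).

Real sensors lose transmission. `regularize()` places a trace on an exact
`interval_min` grid, bridging gaps up to `max_gap_min = 15` minutes by
linear interpolation and splitting at anything longer. The 15-minute
default mirrors the physiological sensor-to-capillary lag bound usually
quoted for CGM (5–15 min): inside it, a straight line is a defensible
bridge; beyond it we refuse to invent data and split instead. Supervised
windows never span segment boundaries.

## 3. Synthetic cohort generator

The reference clinical cohort (8 poorly controlled T1D
patients, >32,000 five-minute samples, pooled mean 8.32 mmol/L, SD 3.51
mmol/L, observed range 2.8–18.2 mmol/L) is not publicly available. The
generator exists so that every downstream stage is testable against data
with the same statistical structure. Each patient is

`clamp( basal + circadian cosine + Σ meal kernels + AR(1) noise )`

* **Meal kernel**: `amp · (t/rise) · exp(1 − t/rise)` — zero at the meal,
  peak `amp` at `t = rise` — blended value-continuously at `t = 2·rise`
  into an exponential tail with time constant `decay`. A gamma-like rise
  with a slower decay is the standard shape of a post-prandial glucose
  excursion; no insulin–glucose ODE model is attempted.
* **AR(1) noise** reproduces the strong short-lag autocorrelation of sensor
  error; with meals and circadian switched off, the lag-1 autocorrelation
  of a generated trace matches `ar_coef` (tested at n = 10,080 ± 0.05).
* **Gaps are deletions**, not missing-value markers, because the real
  failure mode is lost transmission; `regularize()` then has to split,
  which the tests exercise.
* **Calibration entries** are sensor glucose plus N(0, 0.35 mmol/L)
  capillary error at ~1 entry/patient-day, matching the ~123 calibration
  entries of the reference cohort's scale.

**Calibration.** The free constants of the default profile sampler (basal
centre 5.83 mmol/L, meal amplitude U(7.9, 9.5) mmol/L, rise U(40, 50) min,
decay U(80, 100) min, circadian amplitude U(1.2, 1.8) mmol/L, AR
coefficient U(0.80, 0.90), innovation SD U(0.30, 0.40) mmol/L, clamp
2.2–22.2 mmol/L) were fixed once, by a coarse grid over the basal centre
and meal-amplitude centre against the pooled-moment targets, and frozen as
package constants — acceptance does not depend on any online fitting. Over
master seeds 1–16 the worst pooled-mean deviation from 8.32 is 0.10 and the
worst pooled-SD deviation from 3.51 is 0.10.

**Deliberate distortion.** Between-patient heterogeneity is understated
(basal SD 0.06 mmol/L): with only 8 patients, realistic patient-level
spread would make the *pooled cohort* moments fluctuate across seeds far
beyond the calibration tolerances, so the variance is carried instead by
within-patient dynamics (large meal excursions to ~18 mmol/L, overnight
troughs near 3 mmol/L), which average stably over 112 patient-days. A
consequence: a green moment-calibration test says the generator matches
the printed pooled statistics, **not** that it reproduces clinical
inter-patient variability, meal-time irregularity, exercise effects, or
sensor drift. Record length (14 days/patient) is chosen purely to satisfy
the ">32,000 points from 8 patients" arithmetic; per-patient record
lengths are otherwise unconstrained.

## 4. Datasets, splits, scaling

Windows are `(L history samples → target H steps ahead)` pairs;
`n − L − H + 1` per segment of length `n`. Splits are chronological per
patient (default 80/20) so every training target precedes every test
target — shuffled splits would leak the strongly autocorrelated future
into training. The standardizing scaler (pooled mean/SD of training inputs
only) is applied to inputs and targets for conditioning; predictions are
always inverted to mmol/L before any reported error, so MSE stays on the
clinical scale. Default `L = 12` (60 minutes): the reference protocol specifies
only that recent history is used; 12 steps is a round hour, exposed as a knob
and included in the hyperparameter search space.

## 5. Architectures

All six model kinds share: per-step linear embedding of the scalar input
to `d_model`, a sequence core, a final feature vector, a linear head.

The hybrid adds sinusoidal positional encoding (the standard table with
constant 10000; no other formula is prescribed) and a post-norm encoder
stack — attention sublayer, residual, layer norm; feed-forward sublayer,
residual, layer norm — with unmasked multi-head self-attention. Post-norm
matches the stated block order: each sublayer is followed by its residual
connection and then normalization. Two branches read the encoded sequence: positional mean
pooling (default; `"last"` is available) and an LSTM over the encoder
output whose final hidden state is taken. Mean pooling is the default
because with `L = 12` every position carries signal and pooling halves the
sensitivity to the final position that the LSTM branch already emphasizes.
The branch features are concatenated and projected to the scalar.

The LSTM recurrence follows the canonical gate equations (forget, input,
candidate, cell, output, hidden as in the README). Two ambiguities
in the reference equations were resolved to the standard reading: the cell
update is `C_t = f_t ⊙ C_{t−1} + i_t ⊙ C̃_t`, and gate semantics follow the
equations rather than the prose (which inverts the input gate's meaning).
`stacked_lstm` stacks two LSTM layers; `bilstm` concatenates the final
states of a forward and a backward pass; `gru` uses the variant
`n = tanh(W_x x + r ⊙ (W_h h) + b)`.

Default test-scale configuration: `d_model` 16, 2 heads, 2 encoder layers,
FFN 32, LSTM hidden 32, 1 LSTM layer, dropout 0.1 — small enough for CPU
minutes, all searchable.

## 6. The training engine

No deep-learning framework exists in the deployment environment, so
training runs on a package-internal reverse-mode autodiff tape
(`R/autodiff.R`): ~20 matrix ops with hand-derived backward closures,
including fused multi-head attention and row-wise layer normalization.
Design properties worth knowing:

* One forward implementation. The same op functions run with recording on
  (training) or off (evaluation), so there is no separately maintained
  inference path to drift. `hybrid_forward()` is additionally tested to
  equal a manual chain of the exported primitives (`positional_encoding`,
  `transformer_encoder`, `lstm_forward`).
* Gradients of every parameter group of all six architectures are checked
  against central finite differences (tolerance 1e-6 relative; observed
  ~5e-11).
* Numerical guards: softmax rows are max-shifted; layer norm uses
  eps = 1e-5; dropout is inverted (scaled at train time).

Optimization: Adam (β₁ 0.9, β₂ 0.999, ε 1e-8) by default, lr 1e-3, batch
32, up to 200 epochs, early stopping on the chronologically last
`val_frac = 0.2` of the training windows with patience 15, best-validation
parameters restored. The reference protocol specifies only gradient-descent-based
optimization; these defaults finish the synthetic benchmark in minutes.
Everything (shuffling, dropout, init) is seeded; two runs with the same
seed are bit-identical. `max_train_windows` thins very large training sets
by an even deterministic stride — a compute-scale knob used by the test
suite, not a statistical choice.

## 7. Evaluation protocol

`evaluate_horizons()` builds the complete model × horizon grid: windows at
`H = PH/5`, per-patient chronological split, train-fit scaler, seeded
training, test-set MSE in (mmol/L)². A failed cell is recorded as `NA`
and flagged rather than aborting the grid. The persistence baseline
(repeat the last observed value) is the skill gate: on a strongly
autocorrelated signal almost anything correlates with the future, so a
model is only credited when it beats persistence. The Q-Q report uses
Hazen probability points `(i − 0.5)/N` (a convention choice; none is
prescribed) and summarizes linearity by the correlation of the paired
quantiles.

The reference clinical cohort's MSE table (hybrid 1.18/1.70/2.00 at
15/30/45 min) is treated as protocol documentation, not a reproduction
target: it depends on the unavailable hospital data. On the default
synthetic cohort the trained hybrid reaches ~1.12 (mmol/L)² at 15 min
versus ~1.64 for persistence — numbers the README example and the
acceptance tests actually compute.

## 8. Genetic hyperparameter search

The reference protocol names genetic optimization and shows a decreasing
iteration–fitness curve but prescribes no operators. The canonical scheme implemented:
tournament selection (k = 2), uniform crossover, per-gene mutation by
domain resampling, elitism (top `elite_k` copied unchanged) — which makes
the best-so-far curve provably nonincreasing, the one contract the curve
itself exhibits. Fitness is validation MSE (scaled units) of a shortened
training run; the final model should be retrained at full budget. The
`d_model % n_heads == 0` constraint is enforced at sampling and repaired
after mutation by gene resampling. Tests recover a planted optimum on a
64-candidate discrete space against an exhaustive-search oracle.

## 9. Degenerate inputs and numerical edges

* Constant training inputs → `cgm_constant_data` (no scaler exists).
* Zero-variance residuals → Q-Q report refuses (`cgm_degenerate_input`).
* Non-finite training loss → `cgm_divergence_error` naming the epoch.
* `lr = 0` is legal and performs exact null updates (used as a test).
* Ties in the chronological split are impossible by construction
  (timestamps are strictly increasing within a patient); across patients
  `order()`'s stable sort breaks equal target times deterministically.
* Gap arithmetic uses a 1e-9 minute tolerance so grid membership is not
  subject to floating-point jitter.

## 10. What the tests establish, and limits

Green tests establish: exact agreement of the core numerics with
independent oracles (scalar-loop LSTM cell, enumeration window counts,
loop MSE, finite-difference gradients), the architecture's symmetry
properties (permutation equivariance broken exactly by positional
encoding), seeded end-to-end reproducibility, generator moment
calibration, and skill over persistence on the synthetic benchmark at
desk-scale training budgets (thinned windows, ~18 epochs — chosen for the
CPU-minute budget; orderings, not tuned values, are asserted).

They do **not** establish clinical performance: the synthetic cohort lacks
real meal-time irregularity, exercise, sensor drift and inter-patient
heterogeneity, and the interstitial-to-capillary lag is not modelled.
Multi-objective search, covariate channels (insulin, carbohydrate,
activity) and device-specific binary formats are out of scope; calibration
BG is carried through the I/O layer as an optional channel but the default
models are univariate.
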