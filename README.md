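# cgmforecast

Short-horizon blood-glucose forecasting from continuous glucose monitoring
(CGM) traces, built around a hybrid **Transformer-encoder + LSTM** neural
forecaster with five recurrent baselines, a calibrated synthetic CGM cohort
simulator, and genetic hyperparameter search. Everything — including the
reverse-mode autodiff engine that trains the networks — is implemented in R
with no deep-learning framework dependency.

## Who this is for

Researchers and engineers working on diabetes-management analytics who need
a reproducible, testable pipeline for multi-horizon CGM forecasting:
ingesting 5-minute sensor traces, handling signal-loss gaps, building
leak-free supervised datasets, training and comparing sequence models, and
auditing forecast residuals.

## The model

A CGM trace is a series `y(t)` in mmol/L sampled every 5 minutes. Direct
multi-horizon forecasting fits one model per prediction horizon
PH ∈ {15, 30, 45} min (H = 3, 6, 9 steps): given the last L samples
(default L = 12, one hour), predict `ŷ(t | t − PH)`.

The hybrid forecaster embeds each scaled sample, adds sinusoidal positional
encoding `PE(pos, 2i) = sin(pos / 10000^(2i/d))` (cos for odd columns), and
applies post-norm Transformer encoder blocks — unmasked multi-head
self-attention and position-wise feed-forward layers, each with residual
connection and layer normalization. The encoded sequence feeds two
branches: a mean-pooled summary across positions, and an LSTM whose cell
follows the canonical gated recurrence

    f_t = σ(W_f·[h_{t−1}, x_t] + b_f)        (forget gate)
    i_t = σ(W_i·[h_{t−1}, x_t] + b_i)        (input gate)
    C̃_t = tanh(W_C·[h_{t−1}, x_t] + b_C)     (candidate state)
    C_t = f_t ⊙ C_{t−1} + i_t ⊙ C̃_t          (cell state)
    O_t = σ(W_O·[h_{t−1}, x_t] + b_O)        (output gate)
    h_t = O_t ⊙ tanh(C_t)

The pooled summary and the final hidden state `h_L` are concatenated and a
linear head emits the scalar forecast. Baselines (`rnn`, `gru`, `lstm`,
`stacked_lstm`, `bilstm`) share the embedding → recurrent core →
final-state → head skeleton. Forecast quality is scored as
`MSE = (1/N) Σ (ŷ(t | t−PH) − y(t))²` in (mmol/L)², always against the
**persistence baseline** (repeat the last observed value), and residual
normality is audited with a Hazen-point normal Q-Q correlation.

Because the 8-patient hospital dataset the package's benchmarks emulate is
not public, the package ships a calibrated simulator: circadian baseline +
gamma-like meal excursion kernels + AR(1) sensor noise + sparse calibration
entries + signal-loss gaps, whose default 8-patient × 14-day cohort matches
that cohort's reported descriptive statistics (>32,000 samples, pooled mean
≈ 8.32 mmol/L, SD ≈ 3.51 mmol/L).

## Worked example

```r
library(cgmforecast)

# 1. synthetic cohort emulating the reference clinical data
cohort <- simulate_cohort(default_cohort_config(), seed = 1)
print(pooled_summary(cohort))

# 2. windows at the 15-minute horizon (L = 12 history steps, H = 3)
spec <- window_spec(lookback_steps = 12, horizon_steps = 3, interval_min = 5)
sp <- cohort_split_windows(cohort, spec, train_frac = 0.8)
scaler <- fit_scaler(sp$train)

# 3. train the hybrid forecaster
model <- build_model("transformer_lstm", hybrid_config(), seed = 1)
fit <- train(model, apply_scaler(sp$train, scaler),
             train_config(lr = 3e-3, batch_size = 64, max_epochs = 18,
                          patience = 4, seed = 1, max_train_windows = 1200))

# 4. evaluate against the persistence baseline
result <- predict(fit$model, apply_scaler(sp$test, scaler), scaler)
print(result)
cat(sprintf("persistence baseline MSE: %.4f (mmol/L)^2\n",
            mse(persistence_forecast(sp$test))))
print(qq_normality(result))
```

Output (about two CPU minutes):

```
n=32100  mean=8.40  sd=3.41  min=2.20  max=18.22 mmol/L  (110 calibration)
<forecast_result> PH=15 min, N=6329, MSE=1.1208 (mmol/L)^2
persistence baseline MSE: 1.6438 (mmol/L)^2
<qq_report> n=6329, r=0.9168
```

Reading it: the simulated cohort pools 32,100 samples whose moments sit at
the calibration targets; at the 15-minute horizon the trained hybrid
reaches a test MSE of 1.12 (mmol/L)² versus 1.64 for the naive
last-value forecast — the minimal evidence that the network learned
temporal structure — and the Q-Q correlation of 0.92 says the residuals
are roughly Gaussian with heavier-than-normal tails (meal onsets are the
hard-to-predict events).

`evaluate_horizons()` runs the full 6-model × 3-horizon comparison grid and
`genetic_search()` tunes hyperparameters with validation-MSE fitness; both
are exposed through the CLI:

```sh
Rscript inst/cli/cgmforecast simulate --patients 8 --days 14 --seed 1 --out runs/sim
Rscript inst/cli/cgmforecast compare --config run.yaml --out runs/grid
Rscript inst/cli/cgmforecast optimize --config run.yaml --out runs/ga
```

## Package layout

- `R/cgm_io.R` — CSV dialect, validation, gap-aware regularization, summaries
- `R/synthetic.R` — calibrated synthetic CGM cohort generator
- `R/dataset.R` — sliding windows, chronological splits, reversible scaling
- `R/autodiff.R` — minimal reverse-mode autodiff tape (the training engine)
- `R/models.R` — hybrid Transformer-LSTM and the five recurrent baselines
- `R/training.R` — seeded minibatch Adam/SGD with early stopping
- `R/evaluation.R` — MSE, persistence baseline, comparison grid, Q-Q report
- `R/hyperopt.R` — genetic hyperparameter search
- `R/cli.R` — `simulate` / `train` / `compare` / `optimize` commands

See `vignettes/cgmforecast-methods.Rmd` for the modelling assumptions,
calibration procedure, numerical choices and known limitations.
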