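# wtteicu

Real-time cardiac-arrest risk prediction for intensive-care patients,
modelled as a *recurrent Weibull time-to-event problem*: instead of
classifying "event within a fixed window: yes/no", the model maps each
patient's accumulating hourly clinical history to a full probability
distribution over the time remaining until arrest.

## Who this is for

Biostatisticians and clinical-ML researchers who want a tested, reproducible
reference implementation of the deep parametric survival approach to ICU
early warning — including the data preparation conventions (missingness
filters, censoring caps, sliding-window tensors) that published work in this
area usually leaves implicit. Because real ICU records cannot be shared, the
package ships a seeded synthetic cohort generator with the same statistical
structure, so every stage is runnable and testable end to end.

## The model

Each observation is one patient at one prediction hour: a window of up to 48
hourly vectors of 45 clinical variables (right-aligned, left-padded, with
fully-missing hours masked). A gated recurrent unit (GRU) layer of 50 units
reads the window step by step; a 20-unit dense tanh layer and two heads emit
the parameters of a Weibull distribution for the remaining time *T* to
arrest:

```
k = softplus(a),   λ = exp(b),   f(t) = (k/λ)(t/λ)^(k−1) exp(−(t/λ)^k)
```

Training minimises the right-censored negative log-likelihood

```
−ℓ = −u·log f(t) − (1−u)·log S(t),    S(t) = exp(−(t/λ)^k)
```

where `u` indicates an observed arrest and censored remaining times are
capped at a safety threshold τ = 72 h. The network, backpropagation through
time and the Adam optimizer are implemented in compiled code
(`src/gru_engine.cpp`); gradients are verified against finite differences in
the test suite.

Evaluation is horizon-indexed ROC analysis: at each horizon *h* ∈ {1, 8, 16,
24, 32, 40, 48} hours, cases are event observations with *h* hours left,
controls are censored observations still under observation at *h*, both
scored by the predicted probability of arrest within *h* hours (the Weibull
CDF at *h*), pooled over 5-fold patient-level cross-validation.

## Worked example

```r
library(wtteicu)

spec <- cohort_spec(n_event = 32, n_censored = 320, seed = 11)
cohort <- inject_missingness(generate_cohort(spec))

series   <- cohort_series_long(cohort)
patients <- cohort_patient_table(cohort)
features <- select_common_features(series, sprintf("V%02d", 1:45))
stats    <- compute_missingness(features, daily_vars = daily_variables(spec))
keep     <- filter_patients(stats, p_id_max = 1000, p_ir_max = 0.2)
kept     <- patients[patients$patient_id %in% keep, ]

windows <- build_windows(features, kept, horizon_steps = 24, tau = 72,
                         max_windows = 48)
print(windows)
#> Labeled window set: 11552 observations x 24 steps x 45 variables
#>   event observations: 821  censored: 10731
#>   masked steps: 69275 (25.0%)  standardized: FALSE

cfg <- wtte_config(gru_units = 24, dense_units = 10, epochs = 40,
                   batch_size = 128, learning_rate = 0.003,
                   checkpoint = "last", seed = 5)
cv <- run_cv(windows, kept, cfg)
tauc_table(cv$predictions)
```

The printed window set says: 263 retained patients contributed 11,552
(patient, prediction-hour) observations, 821 of them from arrest patients;
a quarter of all window steps are fully unobserved hours the network skips.
The AUC table reports, per horizon, how well the pooled out-of-fold risk
scores separate observations *h* hours before arrest from censored ones —
discrimination is strongest at short horizons, where pre-arrest physiology
is most deranged, and decays as the horizon grows.

A full pipeline (simulation to `tauc.csv` + manifest) is one call:

```r
run_pipeline(run_config(out_dir = "run1", seed = 1))
```

or from a shell via `inst/cli/wtte-icu.R run-all --config cfg.yaml`.

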