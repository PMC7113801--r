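# Small demonstration run: a 12 event / 60 censored synthetic cohort,
# short histories, a small network. Finishes in well under a minute.
cohort:
  n_event: 12
  n_censored: 60
  n_vars: 12
  baseline_scale: 40
  censor_median: 48
  seed: 1
horizon_steps: 12
max_windows: 24
model:
  gru_units: 8
  dense_units: 4
  epochs: 10
  batch_size: 128
  learning_rate: 0.003
  n_folds: 3
  seed: 2
horizons: [1, 8, 16, 24, 32, 40, 48]
seed: 1
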