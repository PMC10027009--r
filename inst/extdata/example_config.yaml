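# Example speckperf configuration override.
# Any key from speckperf_config() can be overridden; missing keys keep their
# package defaults. Units: lengths mm, coefficients mm^-1, speeds mm/s,
# exposures ms, blood fraction %.
tissue_model:
  restricted: false
  c_blood:
    family: truncexp
    support: [0.01, 4.0]
    median: 0.55
  mean_speed:
    family: truncexp
    support: [0.05, 20.0]
    median: 1.0
mc:
  n_photons: 1.0e5
  g_transport: 0
contrast:
  noise:
    eta1: 0.02
    eta_diff: [0.01, 0.01, 0.01, 0.01, 0.01, 0.01]
ann:
  hidden: 25
  restarts: 5
  lr: 3.0e-3
  max_epochs: 3000
dataset:
  n_train_pool: 10000
  n_eval: 10000
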