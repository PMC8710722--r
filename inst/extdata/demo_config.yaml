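# Demo pipeline configuration: three conditions x 10 subjects, 30 s each,
# 64-channel synthetic EEG with a 40 Hz SSVEP over posterior regions in the
# flicker40 condition only.
mode: synthetic
n_subjects: 10
conditions: [rest, random, flicker40]
synthetic:
  n_channels: 64
  sampling_rate: 500
  duration: 30
  n_states: 4
  mean_segment_duration: 60
  alpha_band: [8, 13]
  noise_exponent: 1
  snr: 5
  ssvep:
    frequency: 40
    region_gains: {O: 1.5, PO: 1.0, P: 0.6, CP: 0.25}
    subject_sd: 0.2
preprocessing:
  bandpass: [0.1, 100]
  notch: 50
spectral:
  band: [39, 41]
  total_band: [0.1, 100]
  nw: 4
microstates:
  n_states: 4
  n_restarts: 20
  tol: 1.0e-6
  min_segment_ms: 30
  cluster_band: [8, 13]
  lzc_band: [1, 100]
stats:
  alpha: 0.05
  q: 0.05
seed: 1
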