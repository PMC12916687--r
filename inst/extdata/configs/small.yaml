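# Small synthetic-benchmark configuration: an end-to-end run (simulate ->
# features -> graphs -> LOSO training -> report) sized for a single CPU.
simulation:
  n_subjects: 8
  trials_per_subject: 8
  c: 8
  fs: 128
  duration_s: 30
  effect_band: alpha
  effect_size: 1.0
  n_regions: 2
  within_region_corr: 0.6
  seed: 1
segmentation:
  l_s: 20
  s_s: 4
  scales:
    - [4, 2]
    - [8, 4]
model:
  h: 16
  w_out: 8
  cheb_order: 2
  d_state: 8
training:
  max_epochs: 10
  patience: 5
  seed: 1
protocol:
  type: loso
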