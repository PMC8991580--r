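# Example toothstage pipeline configuration (small smoke-run scale).
seed: 1
out_dir: toothstage-run
synth:
  n_per_stage_per_cohort: 2
  clutter_level: 0.08
  impulse_noise_fraction: 0.02
preprocess:
  side: 250
  kernel: 7
  clahe: false
segment:
  enabled: true
  n_lines: 1200
  radius_length: 100
  delta: 3
augment:
  factor: 10
train:
  optimizer: adam
  learning_rate: 0.001
  epochs: 10
  batch_size: 8
  train_fraction: 0.8
  input_side: 90
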