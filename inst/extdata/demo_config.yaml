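# Demo configuration for run_pipeline(): a small end-to-end label-free
# drug-response experiment (simulate -> train -> predict -> longitudinal
# dose-response). Sized for a quick desk run.
sim:
  channel_width_px: 192
  channel_height_px: 144
  seeding_density: 30
  seeding_cv: 0.2
  growth_rate: 1.08
  drug_ic50: 1.0
  drug_hill: 1.0
  drug_bottom: 0.05
  seed: 7
experiment:
  n_chips: 12
  days: [0, 2, 4, 6, 8]
  doses: [0.0, 0.01, 0.1, 1.0, 10.0, 100.0]
  treat_day: 6
hyper:
  epochs: 10
  batch_size: 4
  lr: 0.002
  crop_px: 64
  patches_per_epoch: 32
  base_filters: 16
  depth: 4
  patience: 100
  seed: 7
segment:
  min_area_px: 20
  aggregate_area_cutoff_px: 200
  smooth_sigma_px: 1
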