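# CPU-scale demonstration configuration for the spihits CLI.
# Toy 64x64 detector (lower panel dead), reduced network, short training.
geometry:
  distance_m: 0.130
  pixel_um: 270
  wavelength_nm: 0.729
  shape: [64, 64]
  center_xy: [31.5, 31.5]
sim:
  particle_radius_range: [27.5, 42.0]
  single_fraction: 0.005
  fluence_jitter: 0.5
  mean_photon_scale: 2000
  background_level: 0.5
model:
  input_size: [32, 16]
  base_filters: 8
  max_filters: 32
  n_blocks: 4
  downsample_plan: [[2, 2], [1, 1], [2, 2], [2, 1]]
  final_size: [4, 4]
train:
  lr0: 5.0e-4
  batch_size: 32
  iterations_per_epoch: 50
  epochs: 40
  p_single_in_batch: 0.02
  n_folds: 5
  augment: ~
inference:
  threshold: 0.5
  tta: true
psd:
  bins: 150
  n_pairs: 3
  scale: log
size:
  low: 55
  high: 84
data:
  n_train_single: 100
  n_train_nonsingle: 3900
  n_test_single: 100
  n_test_nonsingle: 1900
seed: 1
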