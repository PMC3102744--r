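# Example configuration for run_experiment(); load with
# read_experiment_config(). Any experiment_config() argument may be set.
seascape:
  extent_cells: [120, 400]
  cell_size_m: 4
  n_reef_patches: 30
  patch_amplitude_m: 4
species:
  coney:
    steps:
      dist_to_shelf: {location: 600, jump: -4}
    linear: {slope_of_slope: 0.3}
    target_prevalence: 0.1
radii: [5, 25, 50]
n_sites: 600
n_validation_sites: 240
brt:
  learning_rate: 0.05
  max_trees: 300
  cv_eval_stride: 25
n_background: 3000
cv_folds: 10
seed: 1
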