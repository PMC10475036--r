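# Default pipeline configuration: two-group speech-feedback cohort with
# valence-asymmetric learning, four synthetic mediator regions, and a
# 1000-parcel network-similarity stage. All rating units are VAS [0, 1].
seed: 1
generator:
  n_trials: 52
  n_subjects_per_group: {SAD: 21, HC: 23}
  mismatch_sd: 0.15
  rating_noise_sd: 0.05
  esteem_noise_sd: 0.05
  t2_noise_sd: 0.05
  n_regions: 4
  region_paths:
    a_strength: [0.5, 0.5, 0.0, 0.0]
    b_strength: [0.5, 0.0, 0.5, 0.0]
  mediator_noise_sd: 1.0
  mediator_outcome_scale: 0.05
  group_param_distributions:
    SAD:
      beta_pos: [0.40, 0.15]
      beta_neg: [0.55, 0.15]
      prior: [0.40, 0.15]
      alpha_pos: [0.25, 0.15]
      alpha_neg: [0.35, 0.15]
      trait_eval_mean: [0.45, 0.10]
    HC:
      beta_pos: [0.55, 0.15]
      beta_neg: [0.45, 0.15]
      prior: [0.55, 0.15]
      alpha_pos: [0.40, 0.15]
      alpha_neg: [0.25, 0.15]
      trait_eval_mean: [0.55, 0.10]
analysis:
  include_intercept: false
  n_rates: 2
  n_boot: 1000
  alpha: 0.05
network:
  n_parcels: 1000
  frac_in: 0.2
  base_signal: 0.2
  group_effect: 0.8
  bias_slope: 0.5
  signal_noise_sd: 1.0
  noise_sd: 1.0
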