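# Demo pipeline configuration: a small synthetic pan-cancer study that runs
# end to end in a couple of minutes on one CPU.
seed: 42
simulation:
  n_cohorts: 4
  n_mirnas: 20
  n_genes: 80
  samples_per_cohort: 80
  n_planted_training: 60
  n_planted_heldout: 25
  n_planted_undiscovered: 25
ensemble:
  downsample_rates: [0.05, 0.2, 1.0]
  n_models: 10
  freq_thresholds: [7, 8, 9]
validation:
  alpha: 0.05
  rate: 0.2
  freq_threshold: 8
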