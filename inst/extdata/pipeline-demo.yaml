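# Demonstration end-to-end pipeline configuration. Any field omitted here
# falls back to default_pipeline_config(); the single seed drives every
# random stage.
seed: 7
simulate:
  n_users: 400
  background_rate: 0.6
  adopter_fraction: 0.3
  sustained_fraction: 0.07
profile:
  concept: diarrhea
  range_days: 30
classify:
  model: linear_regression
  target_class: all
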