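# Demonstration study configuration: a small synthetic cohort assessed by
# 12 CHWs in a crossover design with the calibrated default error model.
seed: 17
cohort:
  n_infants: 60
  seed: 101
error_model:
  n_chws: 12
  block_size: 6
  assessments_per_infant: 2
  seed: 202
classification:
  small_definition: weight_or_foot
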