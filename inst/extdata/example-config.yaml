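# Example pipeline configuration for inst/scripts/wce-pipeline.R.
# Any field of sim_config() / claims_config() can be set here; unset fields
# keep package defaults. `true_weight_scale: 0` would simulate under a null
# weight function.
claims:
  study_start: 2011-01-01
  study_end: 2015-09-30
sim:
  n_patients: 500
  seed: 1
  true_weight_scale: 1
candidates:
  - window: 75
    knots: 1
    constrained: yes
  - window: 30
    knots: 1
    constrained: yes
  - window: 180
    knots: 1
    constrained: yes
ncc:
  n_controls: 2
  age_caliper: 2
  entry_caliper: 30
  window: 75
  knots: 1
  constrained: yes
heatmap:
  doses: [1, 2, 3, 4]
  durations: [2, 7, 14, 30, 45, 60, 75]
  stop_durations: [2, 7, 30]
  stop_lags: [1, 2, 7, 14, 30, 45, 60, 75]
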