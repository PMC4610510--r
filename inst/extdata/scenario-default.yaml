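# Default synthetic fed-batch scenario / benchmark configuration.
# Any field omitted here falls back to the package defaults
# (see benchmark_config()). Units: h, MHz, pF/cm, 1e5 cells/mL.
clone:
  per_cell_capacitance: 0.7
  critical_frequency_cells: 1.2
  cole_cole_alpha: 0.1
  debris_critical_frequency: 6.0
  debris_amplitude: 0.3
  name: cloneA
amplitude_ratio: 1.4493
debris_fc_ratio: 0.6
culture:
  mu_max: 0.045
  capacity: 160
  death_onset: 144
  death_rate: 0.02
  lysis_rate: 0.03
  duration: 336
  inoculum: 5
disturb:
  bolus_times: [96, 144, 192, 240]
  bolus_fractions: 0.02
  bubble_burst_times: [60, 200]
  bubble_depth: 0.04
  bubble_width: 0.3
  drift_rate: 0.05
  noise_cv: 0.015
  noise_floor: 0.5
  debris_fc_cv: 0.1
sampling:
  online_interval: 0.5
  offline_interval: 12
  offline_cv: 0.05
n_train: 5
n_validation: 6
scaling_mode: mean_center
n_components: 3
lag_time: 6
min_samples: 3
kappa_mode: regression
param_jitter_cv: 0.05
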