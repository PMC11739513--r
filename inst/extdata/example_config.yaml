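# example run configuration: 25-super-lobule synthetic model under
# subnormothermic machine-perfusion boundary conditions
geometry:
  target_volume_ml: 1600
  n_super_lobules: 25
  points_per_sl: 200
  min_points: 5000
  blood_volume_fraction: 0.25
growth:
  D: 5.0
  d_k: 10.0
  d_i: 15.0
flow:
  P_in_mmHg: 5.8
  P_out_mmHg: 0.0
  Q_target_ml_min: 767
  mu_cP: 3.5
  gamma: 3
  root_diameter_mm: 15
perfusion:
  dt_s: 0.01
  thresholds: [0.5, 0.9, 0.98]
seed: 1
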