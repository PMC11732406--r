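# Small demonstration run: a 20 x 20 synthetic city with a negative
# education-occupation effect on mobility change, analysed for two
# scenarios (a strong lockdown-style change and a weaker reopening-style
# change), each against its own pre-pandemic baseline period.
simulate:
  grid_n: 20
  dzn_block: 2
  cell_km: 1
  beta_eo: -0.1
  beta_er: 0.0
  beta_dist: 0.0
  sigma_noise: 0.2
  rho_er_eo: 0.9
  gamma_eo_dist: -0.5
  straddle_frac: 0.04
periods:
  - label: base_spring
    duration_days: 30
    effect_scale: 0
  - label: lockdown
    duration_days: 30
    effect_scale: 1
    panel_rate: 400
  - label: base_summer
    duration_days: 31
    effect_scale: 0
  - label: reopening
    duration_days: 31
    effect_scale: 0.5
    panel_rate: 450
scenarios:
  lockdown:
    test: lockdown
    baseline: base_spring
  reopening:
    test: reopening
    baseline: base_summer
weights_k: 8
mk_method: normal_approx
seed: 1
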