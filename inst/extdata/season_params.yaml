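# Per-season calibration for the Cauvery Delta irrigated rice system.
# Units: K inputs and drawdowns kg K/ha; yields Mg/ha; removal
# coefficients kg nutrient per Mg grain yield; agronomic efficiency
# kg grain per kg fertilizer N.
kuruvai:
  irrigation_k_input: 25
  water_k_conc: 2.6
  k_drawdown_target: -30
  agronomic_efficiency: 15
  attainable_gain: 1.8
  target_increment: 1.0
  target_increment_max: 2.5
  late_establishment_cutoff: "06-15"
  late_penalty: 0.4
samba:
  irrigation_k_input: 8
  water_k_conc: 2.6
  k_drawdown_target: -33
  agronomic_efficiency: 14
  attainable_gain: 1.82
  target_increment: 1.0
  target_increment_max: 2.5
thaladi:
  irrigation_k_input: 4
  water_k_conc: 2.6
  k_drawdown_target: -4
  agronomic_efficiency: 14
  attainable_gain: 1.82
  target_increment: 1.0
  target_increment_max: 2.5
  prev_crop_yield: 4.8
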