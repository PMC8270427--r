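{
  "guilds": {
    "fungi": {
      "k_base": 0.413780626490707,
      "t_opt_c": 25,
      "t_sigma_c": 10,
      "t_threshold_c": {},
      "substrate_hardwood": 1,
      "substrate_softwood": 0.95,
      "colonization_lag_d": 1599.95676221329,
      "lag_shape": 0.65,
      "resource_decline": 0,
      "pulse_share": 0,
      "pulse_decline": 0,
      "fragmentation_share": 0.05
    },
    "termites": {
      "k_base": 0.246480308462242,
      "t_opt_c": 28,
      "t_sigma_c": 7,
      "t_threshold_c": 10,
      "substrate_hardwood": 0.85,
      "substrate_softwood": 1,
      "colonization_lag_d": 0,
      "lag_shape": 1,
      "resource_decline": 0.00524815329901836,
      "pulse_share": 0.45,
      "pulse_decline": 2.5,
      "fragmentation_share": 0.3
    },
    "bacteria": {
      "k_base": 0.00613277984476945,
      "t_opt_c": 30,
      "t_sigma_c": 12,
      "t_threshold_c": {},
      "substrate_hardwood": 1,
      "substrate_softwood": 1,
      "colonization_lag_d": 0,
      "lag_shape": 1,
      "resource_decline": 0,
      "pulse_share": 0,
      "pulse_decline": 0,
      "fragmentation_share": 0
    },
    "beetles": {
      "k_base": 0.0488721492080776,
      "t_opt_c": 24,
      "t_sigma_c": 8,
      "t_threshold_c": 8,
      "substrate_hardwood": 1,
      "substrate_softwood": 1,
      "colonization_lag_d": 0,
      "lag_shape": 1,
      "resource_decline": 0.8,
      "pulse_share": 0,
      "pulse_decline": 0,
      "fragmentation_share": 0.4
    }
  },
  "size_exponent": 0.0922532437914217,
  "d_ref_cm": 10,
  "standing_multiplier": 0.6,
  "doc_leach_coeff": 0.0109280154096678,
  "poc_coeff": 0.00018,
  "forest_floor_k": 1.5,
  "doc_retention": 0.853,
  "carbon_fraction": 0.492
}
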