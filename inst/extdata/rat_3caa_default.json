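{
  "physiology": {
    "body_weight": 0.225,
    "cardiac_output_coeff": 14,
    "cardiac_output_exponent": 0.74,
    "alveolar_ventilation_coeff": 14,
    "flow_fractions": {
      "liver": 0.183,
      "fat": 0.07,
      "bone_marrow": 0.03,
      "richly": 0.47,
      "slowly": 0.247
    },
    "volume_fractions": {
      "liver": 0.034,
      "fat": 0.07,
      "bone_marrow": 0.03,
      "richly": 0.05,
      "slowly": 0.727
    }
  },
  "chemical": {
    "molecular_weight": 92.52,
    "p_blood_air": 1492,
    "p_tissue_blood": {
      "liver": 0.95,
      "fat": 1.47,
      "bone_marrow": 1.06,
      "richly": 0.95,
      "slowly": 0.64
    },
    "ka": 1
  },
  "metabolism": {
    "vmaxc": 1808,
    "km": 15
  }
}
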