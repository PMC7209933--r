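{
  "intercept": -0.096,
  "coefficients": {
    "scl_tonic": 0.053,
    "scr_count": 0.024,
    "hr": 0.002,
    "rr": 0.012,
    "sweat": 0.348,
    "ha_neg": 0.095,
    "ha_pos": 0.06,
    "la_neg": -0.071,
    "la_pos": -0.08
  },
  "sweat_unit": "g"
}
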