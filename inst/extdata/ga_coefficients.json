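{
  "version": "final-pilot-v1",
  "feature_units": "pixels_percent",
  "mapping": {
    "branch_length_max": "branch_length_max",
    "branch_width_max": "branch_extent_max",
    "branch_width_min": "branch_extent_min",
    "branch_thickness_max": "branch_width_max",
    "branch_thickness_min": "branch_width_min",
    "density": "density"
  },
  "intercept": 34.406,
  "coefficients": {
    "branch_length_max": 0.022,
    "branch_width_max": -0.092,
    "branch_width_min": 0.155,
    "branch_thickness_max": -0.122,
    "branch_thickness_min": -1.667,
    "density": -0.124
  }
}
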