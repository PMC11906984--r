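{
  "n_women": 2000,
  "seed": 7,
  "models": ["linear", "cubic_polynomial", "bct_cubic_spline", "bct_pspline"],
  "profiles": [
    {"age_years": 28.4, "bmi": 21.7,
     "ethnicity_region": "Australian/European", "parity_class": "0"},
    {"age_years": 32.0, "bmi": 27.5,
     "ethnicity_region": "South central Asian", "parity_class": "1-3"}
  ]
}
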