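{
  "schema_version": "1.0",
  "seed": 1,
  "scenario": "full",
  "n_mice": 5,
  "include_dropouts": false,
  "metabolites": true,
  "observation": {
    "read_depth": 50000,
    "qpcr_cv": 0.25,
    "detection_limit": 1000,
    "stool_mass_mean": 0.05,
    "stool_mass_cv": 0.2,
    "dilution_factor": 100
  },
  "analysis": {
    "alpha": 0.05,
    "min_weight": 0.1,
    "network_day": 16.1,
    "perturbation_days": [16.1, 30.1]
  }
}
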