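{
  "beta0": 0.266,
  "diet_offsets": [0, -0.072, -0.136],
  "beta_L2": 0.101,
  "beta_S": -0.104,
  "beta_R": -0.05,
  "sigma_fish": 0.431,
  "sigma_replicate": 0.183
} 
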