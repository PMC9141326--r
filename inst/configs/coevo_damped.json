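{
  "system": "lv_coevo",
  "alpha0": 1.0, "beta0": 0.1, "gamma0": 1.5, "delta0": 0.075,
  "conversion": 0.75,
  "V1": 0.5, "V2": 0.5, "c1": 0.5, "c2": 0.5,
  "x0": 10, "y0": 5, "u0": 0, "v0": 0,
  "t_end": 200, "n_out": 4000
}
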