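{
  "system": "lv",
  "alpha0": 1.0, "beta0": 0.1, "gamma0": 1.5, "delta0": 0.075,
  "x0": 10, "y0": 5,
  "t_end": 100, "n_out": 2000
}
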