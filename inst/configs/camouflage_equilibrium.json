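{
  "d": 1,
  "background": {"means": [[0.0]], "cov_scale": 1.0, "weights": [1.0]},
  "generator": {"means": [[0.0]], "cov_scale": 1.0, "weights": [1.0]},
  "freeze_generator": false,
  "window": 20, "tol": 0.05, "max_iters": 2000
}
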