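{
  "L": 8, "pop_size": 50,
  "mutation_rate": 0.005, "crossover_rate": 0.7,
  "selection": "proportional",
  "memory_lambda": 0.0, "repro_exponent": 0.0,
  "lifetime_samples": 50, "generations": 300
}
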