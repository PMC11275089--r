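{
  "n_per_group": 25,
  "seed": 20240720,
  "balanced_age": false
}
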