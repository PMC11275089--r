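{
  "membrane": {
    "Cm": 0.5,
    "gNa": 120,
    "gK": 36,
    "gL": 0.3,
    "ENa": 50,
    "EK": -77,
    "EL": -54.387
  },
  "axon": {
    "n_nodes": 9,
    "g_axial": 0.5,
    "dielectric_node": 5,
    "stimulus_node": "all"
  },
  "stimulus": {
    "amplitude": 6.5,
    "t_on": 0,
    "t_off": 500
  },
  "dielectric": {
    "mode": "both",
    "C_user": 0.5,
    "kappa": 0.15,
    "generator_law": "proportional"
  },
  "simulation": {
    "duration": 500,
    "dt": 0.01
  }
}
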