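{
  "delta_psi_mV": 100,
  "delta_ph": 0.4,
  "o2_conc_M": 0.0005,
  "enzyme_conc_mM": 0.001,
  "noise_sd": 0.002,
  "n_points": 400,
  "seed": 1
}
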