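{
  "analyte": "carbendazim",
  "peaks": [630, 728, 1000, 1218, 1260, 1315],
  "tolerance_cm1": 5
}
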