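{
  "sma_broca_left": ["SMA", "BA_L"],
  "premotor": ["PreMA_L", "PreMA_R"],
  "angular": ["AG_L", "AG_R"],
  "wernicke_broca_right": ["BA_R", "WA_L", "WA_R"],
  "supramarginal": ["SMG_L", "SMG_R"]
}
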