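{
  "pentagon": ["SMA", "PreMA_L", "PreMA_R", "WA_L", "WA_R"],
  "broca": ["BA_L", "BA_R"],
  "angular": ["AG_L", "AG_R"],
  "supramarginal": ["SMG_L", "SMG_R"]
}
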