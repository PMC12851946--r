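{
  "immune": {
    "name": "immune_effector",
    "genes": ["GZMB", "IFNG", "CD8A", "PRF1", "CXCL13"],
    "weights": [1, 1, 1, 1, 1]
  },
  "inflammatory": {
    "name": "inflammatory",
    "genes": ["TNF", "IL1B", "IL6", "NFKB1", "PTGS2"],
    "weights": [1, 1, 1, 1, 1]
  },
  "rankl": {
    "name": "rankl_axis",
    "genes": ["TNFSF11", "TNFRSF11B", "TNF"],
    "weights": [1, 1, 1]
  },
  "steroid": {
    "name": "steroid_response",
    "genes": ["NR3C1", "FKBP5", "TSC22D3"],
    "weights": [1, 1, 1]
  },
  "chemo": {
    "name": "chemo_response",
    "genes": ["MKI67", "TOP2A", "TYMS", "AURKA"],
    "weights": [1, 1, 1, 1]
  }
}
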