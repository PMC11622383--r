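{
  "rules": {
    "K": {"n15N": 1, "n13C": 0, "units": [1]},
    "G": {"n15N": 1, "n13C": 2, "units": [1, 2]},
    "S": {"n15N": 1, "n13C": 0, "units": [1]}
  },
  "extras": []
}
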