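{
  "rules": {
    "V": {"n15N": 1, "n13C": 5, "units": [1, 5]},
    "I": {"n15N": 1, "n13C": 0, "units": [1]},
    "L": {"n15N": 1, "n13C": 0, "units": [1]}
  },
  "extras": []
}
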