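{
  "type": "biconcave",
  "d": 0.9,
  "ratios": [0.18, 0.62, 0.35]
}
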