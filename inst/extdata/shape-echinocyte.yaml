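# spiculated desk-scale echinocyte
type: spiculated
d: 0.6
spicule:
  amplitude: 0.05
  n_spicules: 20
  base_halfwidth: 15
  seed: 7
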