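name: C9
costs:
  low: 1
  medium_low: 10
  medium_high: 100
  high: 1000
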