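seed: 1
alpha: 0.05
shift_threshold: 0.15
carbonate:
  kh: 0.0339
  pk1: 6.35
  pk2: 10.33
  temperature: 298.15
  v_liquid: 0.005
  v_gas: 0.020
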