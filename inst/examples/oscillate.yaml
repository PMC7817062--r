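model: oscillator
seed: 1
params:
  a: 0.3
modulation:
  a_bar: 0.3
  delta_a: 0.2
  kappa: 5
experiment:
  k_X: 1.7
  t_end: 100
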