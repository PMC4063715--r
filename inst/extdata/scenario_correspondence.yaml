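# Cross-formulation fitness agreement on the reference semelparous mix.
family: two_resource_gbm
params:
  m1: 0.3
  m2: 0.1
  s1: 0.2
  s2: 0.05
  mu0: 0.1
  x0: 1.0
  xm: 3.0
  q: 2.0
  b0: 0.1
  alpha: 0.4
  omega: 30.0
  breeding: semelparous
analyses: [correspondence]
seed: 1
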