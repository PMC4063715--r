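# Reference two-resource life history (semelparous, generalist regime).
# Sizes are in units of the initial size; rates are per unit age.
family: two_resource_gbm
params:
  m1: 0.2        # drift of R1 (high risk / high return)
  m2: 0.1        # drift of R2 (low risk / low return)
  s1: 0.5        # diffusion intensity of R1
  s2: 0.2        # diffusion intensity of R2
  mu0: 0.05      # baseline mortality (control-free)
  x0: 1.0        # initial size
  xm: 5.656854249492381   # mature size (convexity index 0.4)
  q: 2.0         # fertility released at maturation
  b0: 0.1        # allometric fertility coefficient (iteroparous use)
  alpha: 0.4     # allometric exponent (iteroparous use)
  omega: 30.0    # maximum lifespan (iteroparous use)
  breeding: semelparous
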