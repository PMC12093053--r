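# Fragmentational purging, fragmentation-favoring conditions.
# Budding at tumor-free regions (f1 >> f3), long vulnerable larval period.
name: FRPG-FR
phi: 0.5
I: 0.5
theta: 0.7
s: 1.5
eta0: 0.05
lambda: 3.0
f: [5.0, 1.0, 0.5]
TU: 35
TF: 15
deltaV: 0.7
deltaW: 0.5
r: [1.0, 0.5, 0.1]
offspring_per_fragmentation: 1
fitness:
  omega0: 1.0
  alphaN: 1.0
  alphaD: 0.8
  alphaC: 0.0
  epsilon: 2.0
  tau: 0.8
  delta: 0.5
  c0: 1.0
  b0: 0.7
regulation:
  k: 20.0
  rule: ratio
provenance:
  f: printed
  TU: printed
  TF: printed
  deltaV: printed
  deltaW: printed
  fitness.epsilon: printed
  eta0: reconstructed
  lambda: reconstructed
  r: reconstructed
  fitness.omega0: reconstructed
  fitness.alphaN: reconstructed
  fitness.alphaD: reconstructed
  fitness.alphaC: reconstructed
  fitness.tau: reconstructed
  fitness.delta: reconstructed
  fitness.c0: reconstructed
  fitness.b0: reconstructed
  regulation.k: reconstructed
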