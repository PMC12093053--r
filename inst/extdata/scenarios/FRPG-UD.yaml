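# Fragmentational purging, but unitary development wins: benign tumors
# (epsilon near 1), mild external damage, harsh diversity-loss penalty,
# safe juvenile period.
name: FRPG-UD
phi: 0.0
I: 0.5
theta: 0.0
s: 0.5
eta0: 0.05
lambda: 3.0
f: [1.5, 1.0, 0.4]
TU: 35
TF: 25
deltaV: 0.9
deltaW: 0.8
r: [1.0, 0.2, 0.1]
offspring_per_fragmentation: 1
fitness:
  omega0: 1.0
  alphaN: 1.0
  alphaD: 0.8
  alphaC: 0.0
  epsilon: 1.1
  tau: 0.3
  delta: 0.1
  c0: 1.0
  b0: 0.1
regulation:
  k: 20.0
  rule: ratio
provenance:
  fitness.epsilon: printed
  fitness.tau: printed
  fitness.delta: printed
  fitness.b0: printed
  f: reconstructed
  TU: reconstructed
  TF: reconstructed
  deltaV: reconstructed
  deltaW: reconstructed
  eta0: reconstructed
  lambda: reconstructed
  r: reconstructed
  fitness.omega0: reconstructed
  fitness.alphaN: reconstructed
  fitness.alphaD: reconstructed
  fitness.alphaC: reconstructed
  fitness.c0: reconstructed
  regulation.k: reconstructed
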