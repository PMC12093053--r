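# Fragmentational accumulation (mobile tumor cells, f3 dominant), yet
# fragmentation wins: severe juvenile mortality and frequent external
# damage outweigh the accumulating cancer load.
name: FRAC-FR
phi: 0.5
I: 0.5
theta: 0.7
s: 1.5
eta0: 0.05
lambda: 3.0
f: [1.0, 1.0, 1.3]
TU: 35
TF: 15
deltaV: 0.2
deltaW: 0.15
r: [1.0, 0.5, 0.1]
offspring_per_fragmentation: 1
fitness:
  omega0: 2.0
  alphaN: 1.0
  alphaD: 0.8
  alphaC: 0.0
  epsilon: 2.0
  tau: 0.8
  delta: 0.5
  c0: 0.5
  b0: 0.7
regulation:
  k: 20.0
  rule: ratio
provenance:
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
  fitness.epsilon: reconstructed
  fitness.tau: reconstructed
  fitness.delta: reconstructed
  fitness.c0: reconstructed
  fitness.b0: reconstructed
  regulation.k: reconstructed
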