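# Fragmentational accumulation with safe juvenility and mild damage:
# exclusive sexual reproduction with soma-protective fidelity wins.
name: FRAC-UD
phi: 0.0
I: 0.5
theta: 0.0
s: 0.5
eta0: 0.05
lambda: 3.0
f: [1.0, 1.0, 2.0]
TU: 35
TF: 15
deltaV: 0.9
deltaW: 0.85
r: [1.0, 0.5, 0.1]
offspring_per_fragmentation: 1
fitness:
  omega0: 1.0
  alphaN: 1.0
  alphaD: 0.8
  alphaC: 0.0
  epsilon: 2.0
  tau: 0.2
  delta: 0.1
  c0: 1.0
  b0: 0.3
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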