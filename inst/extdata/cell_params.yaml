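# Nominal rate constants (days^-1) for the two-compartment model, by tissue,
# and global defaults for the dosing problem. gamma: proliferation; delta:
# proliferative death; alpha: P->Q transfer; beta: Q->P transfer; lambda:
# quiescent death.
tissues:
  bone_marrow:
    gamma: 1.470
    delta: 0.000
    alpha: 5.643
    beta: 0.480
    lambda: 0.164
  breast:
    gamma: 0.500
    delta: 0.477
    alpha: 0.218
    beta: 0.050
    lambda: 0.000
  ovarian:
    gamma: 0.6685
    delta: 0.4597
    alpha: 0.2225
    beta: 0.0500
    lambda: 0.0000
global:
  # s and b are calibration constants of the dosing problem, not measured
  # rates; results that depend on them are calibration-dependent.
  s: 1.0
  b: 1.0
  T: 21
  dt: 1
  actions: [0.0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0]
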